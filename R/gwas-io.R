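# Header synonyms accepted by readSummaryStats, all matched case-insensitively
# after stripping non-alphanumerics. Keyed by canonical name.
.COLUMN_SYNONYMS <- list(
  variant_id    = c("variantid", "snp", "rsid", "rsids", "id", "variant",
                    "markername"),
  chromosome    = c("chromosome", "chr", "chrom"),
  position      = c("position", "pos", "bp", "basepairlocation"),
  effect_allele = c("effectallele", "ea", "a1", "allele1", "alt"),
  other_allele  = c("otherallele", "oa", "nea", "noneffectallele", "a2",
                    "allele2", "ref"),
  eaf           = c("eaf", "af", "effectallelefrequency", "freq", "frq"),
  beta          = c("beta", "b", "effect", "effectsize", "es"),
  se            = c("se", "stderr", "standarderror", "sebeta"),
  pval          = c("pval", "p", "pvalue", "pv"),
  n             = c("n", "samplesize", "ntotal", "nsample")
)

.REQUIRED_COLS <- c("variant_id", "effect_allele", "other_allele", "beta",
                    "se", "pval")

.normalizeHeader <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Construct an AssociationTable from a data.frame
#'
#' Validates each row against the per-variant invariants (single-base distinct
#' alleles, `se > 0`, `pval` in (0, 1], `eaf` strictly inside (0, 1) when
#' present, `n >= 2`) and drops failing rows into the rejection log with a
#' reason. Missing `chromosome`, `position`, `eaf` or `n` columns are filled
#' with `NA`; the remaining columns are mandatory.
#'
#' @param df data.frame with (a subset of) the canonical columns.
#' @param traitLabel free-text trait name.
#' @param traitType `"binary"` (beta on the log-odds scale) or
#'   `"continuous"` (standardized units).
#' @return An [AssociationTable-class] object.
#' @export
AssociationTable <- function(df, traitLabel = "trait",
                             traitType = c("continuous", "binary")) {
  traitType <- match.arg(traitType)
  missing_cols <- setdiff(.REQUIRED_COLS, names(df))
  if (length(missing_cols))
    mrStop("mr_missing_column",
           paste("required column(s) missing:",
                 paste(missing_cols, collapse = ", ")),
           columns = missing_cols)
  for (opt in c("chromosome", "position", "eaf", "n"))
    if (!opt %in% names(df)) df[[opt]] <- NA
  df <- df[, .ASSOC_COLS, drop = FALSE]
  df$variant_id <- as.character(df$variant_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- suppressWarnings(as.integer(df$position))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (num in c("eaf", "beta", "se", "pval"))
    df[[num]] <- suppressWarnings(as.numeric(df[[num]]))
  df$n <- suppressWarnings(as.integer(round(as.numeric(df$n))))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(is.na(df$variant_id) | df$variant_id == "", "missing variant_id")
  flag(!df$effect_allele %in% .BASES | !df$other_allele %in% .BASES,
       "allele not a single base in {A,C,G,T}")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(!is.finite(df$beta), "non-numeric beta")
  flag(!is.finite(df$se) | df$se <= 0, "se not > 0")
  flag(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
       "pval outside (0, 1]")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0, 1)")
  flag(!is.na(df$n) & df$n < 2, "n < 2")
  flag(duplicated(df$variant_id), "duplicate variant_id")

  bad <- !is.na(reason)
  rejected <- data.frame(variant_id = df$variant_id[bad],
                         reason = reason[bad],
                         stringsAsFactors = FALSE)
  kept <- df[!bad, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0)
    mrStop("mr_empty_table", "no valid rows after validation",
           rejected = rejected)
  new("AssociationTable", variants = kept, traitLabel = traitLabel,
      traitType = traitType, rejected = rejected)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited file with a header row, resolves common
#' column-name synonyms (e.g. `rsid`/`SNP`, `ea`/`effect_allele`, `b`/`beta`,
#' `p`/`pval`) to the canonical names, and validates every row. Rows failing a
#' type invariant are dropped and listed, with reasons, in the returned
#' object's rejection log ([rejectedRows()]). Indels and multi-base alleles
#' are rejected at read time: downstream palindrome logic is defined only for
#' single-nucleotide variants.
#'
#' @param path file path; delimiter inferred from the header line.
#' @param columnMap optional named character vector mapping canonical names to
#'   source column names, overriding synonym resolution (e.g.
#'   `c(beta = "log_odds")`).
#' @param traitLabel,traitType see [AssociationTable()].
#' @return An [AssociationTable-class] object.
#' @export
readSummaryStats <- function(path, columnMap = NULL, traitLabel = basename(path),
                             traitType = c("continuous", "binary")) {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  norm <- .normalizeHeader(names(raw))
  out <- list()
  for (canon in names(.COLUMN_SYNONYMS)) {
    src <- NA_character_
    if (!is.null(columnMap) && canon %in% names(columnMap)) {
      src <- columnMap[[canon]]
      if (!src %in% names(raw))
        mrStop("mr_missing_column",
               sprintf("mapped column '%s' (for '%s') not in file", src, canon),
               columns = canon)
    } else {
      hit <- which(norm %in% .COLUMN_SYNONYMS[[canon]])
      if (length(hit)) src <- names(raw)[hit[1L]]
    }
    if (!is.na(src)) out[[canon]] <- raw[[src]]
  }
  missing_req <- setdiff(.REQUIRED_COLS, names(out))
  if (length(missing_req))
    mrStop("mr_missing_column",
           paste("no source column found for:",
                 paste(missing_req, collapse = ", ")),
           columns = missing_req)
  AssociationTable(as.data.frame(out, stringsAsFactors = FALSE),
                   traitLabel = traitLabel, traitType = traitType)
}

#' Write an AssociationTable to a TSV file
#'
#' @param object an [AssociationTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(object, path) {
  stopifnot(is(object, "AssociationTable"))
  utils::write.table(object@variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct an LDMatrix from a square r-squared matrix
#'
#' @param r2 square numeric matrix of squared correlations; row and column
#'   names are the variant labels.
#' @param ids optional character vector of labels when `r2` carries none.
#' @return An [LDMatrix-class] object.
#' @export
LDMatrix <- function(r2, ids = NULL) {
  r2 <- as.matrix(r2)
  if (!is.null(ids)) dimnames(r2) <- list(ids, ids)
  new("LDMatrix", r2 = r2)
}

#' Read an LD (r-squared) matrix from a TSV file
#'
#' Expects variant labels in the first row and first column.
#'
#' @param path file path.
#' @return An [LDMatrix-class] object.
#' @export
readLDMatrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1L, check.names = FALSE))
  LDMatrix(m)
}

#' Write an LDMatrix to a TSV file
#'
#' @param object an [LDMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLDMatrix <- function(object, path) {
  stopifnot(is(object, "LDMatrix"))
  utils::write.table(object@r2, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
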