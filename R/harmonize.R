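#' Construct HarmonizedInstruments from an aligned data.frame
#'
#' Low-level constructor for callers (simulations, tests) that already hold
#' exposure and outcome effects on a shared effect allele. Computes the
#' per-SNP Wald ratio and its first-order standard error.
#'
#' @param df data.frame with at least `variant_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`; optional `eaf_*`, `n_*`, `pval_*`, alleles and
#'   coordinates are filled with `NA` when absent.
#' @param exposureLabel,outcomeLabel trait names.
#' @param exclusions optional data.frame (`variant_id`, `reason`).
#' @return A [HarmonizedInstruments-class] object.
#' @export
HarmonizedInstruments <- function(df, exposureLabel = "exposure",
                                  outcomeLabel = "outcome",
                                  exclusions = NULL) {
  need <- c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    mrStop("mr_missing_column",
           paste("required column(s) missing:",
                 paste(missing_cols, collapse = ", ")))
  defaults <- list(chromosome = NA_character_, position = NA_integer_,
                   effect_allele = NA_character_, other_allele = NA_character_,
                   eaf_exp = NA_real_, pval_exp = NA_real_, n_exp = NA_integer_,
                   eaf_out = NA_real_, pval_out = NA_real_, n_out = NA_integer_)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  if (any(df$beta_exp == 0))
    mrStop("mr_zero_exposure_effect",
           "beta_exp must be non-zero for every instrument")
  df$wald_ratio <- df$beta_out / df$beta_exp
  df$wald_se <- df$se_out / abs(df$beta_exp)
  cols <- c("variant_id", "chromosome", "position", "effect_allele",
            "other_allele", "beta_exp", "se_exp", "eaf_exp", "pval_exp",
            "n_exp", "beta_out", "se_out", "eaf_out", "pval_out", "n_out",
            "wald_ratio", "wald_se")
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  if (is.null(exclusions))
    exclusions <- data.frame(variant_id = character(), reason = character(),
                             stringsAsFactors = FALSE)
  new("HarmonizedInstruments", instruments = df, exclusions = exclusions,
      exposureLabel = exposureLabel, outcomeLabel = outcomeLabel)
}

#' Harmonize exposure and outcome GWAS to a shared effect allele
#'
#' Aligns every variant shared by the two tables to the exposure's effect
#' allele. For each shared variant: an identical allele pair is kept as is;
#' a swapped pair has the outcome beta negated and its allele frequency
#' replaced by one minus itself; a strand-complement pair is complemented
#' first and then treated by the same rules; an incompatible pair is dropped.
#' Palindromic variants (A/T or G/C), whose strand cannot be resolved from
#' allele letters, are first aligned nominally by letter and then checked
#' against allele frequencies: the variant is retained only when both
#' frequencies fall outside the ambiguity window on the same side, otherwise
#' it is dropped with reason `"palindromic-ambiguous"`. The exposure
#' orientation is never altered. Every input variant lands exactly once in
#' either the instrument table or the exclusion log.
#'
#' @param exposure,outcome [AssociationTable-class] objects.
#' @param ambiguityWindow numeric pair: allele frequencies inside
#'   `(low, high)` are considered uninformative for palindrome resolution.
#' @param palindromicMode `"infer"` (frequency-based resolution, the default)
#'   or `"drop"` (strict mode: every palindromic variant is excluded).
#' @return A [HarmonizedInstruments-class] object.
#' @export
harmonize <- function(exposure, outcome, ambiguityWindow = c(0.42, 0.58),
                      palindromicMode = c("infer", "drop")) {
  stopifnot(is(exposure, "AssociationTable"), is(outcome, "AssociationTable"))
  palindromicMode <- match.arg(palindromicMode)
  if (length(ambiguityWindow) != 2L || ambiguityWindow[1] > ambiguityWindow[2])
    mrStop("mr_invalid_config", "ambiguityWindow must be an ordered pair")
  ex <- exposure@variants
  ou <- outcome@variants
  shared <- intersect(ex$variant_id, ou$variant_id)
  if (length(shared) == 0L)
    mrStop("mr_no_overlap", "no variants shared between exposure and outcome")

  excl <- list()
  drop <- function(id, why)
    excl[[length(excl) + 1L]] <<- data.frame(variant_id = id, reason = why,
                                             stringsAsFactors = FALSE)
  only_x <- setdiff(ex$variant_id, shared)
  if (length(only_x)) drop(only_x, "absent-in-outcome")
  only_y <- setdiff(ou$variant_id, shared)
  if (length(only_y)) drop(only_y, "absent-in-exposure")

  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]

  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    id <- shared[i]
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    beta_y <- ou$beta[i]; eaf_y <- ou$eaf[i]

    if (.isPalindromic(ea_x, oa_x)) {
      if (palindromicMode == "drop") { drop(id, "palindromic-strict"); next }
      if (ea_y == ea_x && oa_y == oa_x) {
        flip <- FALSE
      } else if (ea_y == oa_x && oa_y == ea_x) {
        flip <- TRUE
      } else { drop(id, "incompatible-alleles"); next }
      if (flip) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y }
      if (is.na(ex$eaf[i]) || is.na(eaf_y)) {
        drop(id, "palindromic-missing-eaf"); next
      }
      lo <- ambiguityWindow[1]; hi <- ambiguityWindow[2]
      same_side <- (ex$eaf[i] < lo && eaf_y < lo) ||
                   (ex$eaf[i] > hi && eaf_y > hi)
      if (!same_side) { drop(id, "palindromic-ambiguous"); next }
    } else {
      cea <- .complementBase(ea_y); coa <- .complementBase(oa_y)
      if (ea_y == ea_x && oa_y == oa_x) {
        flip <- FALSE
      } else if (ea_y == oa_x && oa_y == ea_x) {
        flip <- TRUE
      } else if (cea == ea_x && coa == oa_x) {
        flip <- FALSE
      } else if (cea == oa_x && coa == ea_x) {
        flip <- TRUE
      } else { drop(id, "incompatible-alleles"); next }
      if (flip) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y }
    }

    if (ex$beta[i] == 0) { drop(id, "zero-exposure-effect"); next }
    rows[[i]] <- data.frame(
      variant_id = id, chromosome = ex$chromosome[i],
      position = ex$position[i], effect_allele = ea_x, other_allele = oa_x,
      beta_exp = ex$beta[i], se_exp = ex$se[i], eaf_exp = ex$eaf[i],
      pval_exp = ex$pval[i], n_exp = ex$n[i],
      beta_out = beta_y, se_out = ou$se[i], eaf_out = eaf_y,
      pval_out = ou$pval[i], n_out = ou$n[i], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (length(rows) == 0L)
    mrStop("mr_empty_selection", "no variants survived harmonization",
           stage = "harmonize", exclusions = exclusions)
  HarmonizedInstruments(do.call(rbind, rows),
                        exposureLabel = exposure@traitLabel,
                        outcomeLabel = outcome@traitLabel,
                        exclusions = exclusions)
}

#' Export harmonized instruments as TSV files
#'
#' Writes the instrument table and, optionally, the exclusion log.
#'
#' @param object a [HarmonizedInstruments-class].
#' @param path instrument table path.
#' @param exclusionPath optional exclusion log path (`variant_id`, `reason`).
#' @return `path`, invisibly.
#' @export
writeInstruments <- function(object, path, exclusionPath = NULL) {
  stopifnot(is(object, "HarmonizedInstruments"))
  utils::write.table(object@instruments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(exclusionPath))
    utils::write.table(object@exclusions, exclusionPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a harmonized instrument table written by [writeInstruments()]
#'
#' @param path TSV path.
#' @return A [HarmonizedInstruments-class] object.
#' @export
readInstruments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$chromosome <- as.character(df$chromosome)
  HarmonizedInstruments(df)
}
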