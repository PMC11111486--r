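#' @import methods
NULL

# Canonical per-variant columns of an association table. chromosome, position,
# eaf and n may be NA; the remaining fields are mandatory at read time.
.ASSOC_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                 "other_allele", "eaf", "beta", "se", "pval", "n")

.BASES <- c("A", "C", "G", "T")

#' AssociationTable: per-variant GWAS summary statistics for one trait
#'
#' Holds one GWAS's per-SNP association records: variant identifier,
#' chromosome and 1-based position (both optional, chromosome an uninterpreted
#' label), effect and other allele (single bases), effect-allele frequency,
#' effect size `beta` (log-odds for a binary trait, standardized units for a
#' continuous one), its standard error, p-value and per-SNP sample size.
#'
#' @slot variants data.frame with the canonical columns (see
#'   [readSummaryStats()]); one row per variant, `variant_id` unique.
#' @slot traitLabel single character, free-text trait name.
#' @slot traitType `"binary"` or `"continuous"`.
#' @slot rejected data.frame of input rows dropped at validation time, with a
#'   `reason` column.
#' @export
setClass("AssociationTable",
  representation(variants = "data.frame", traitLabel = "character",
                 traitType = "character", rejected = "data.frame"),
  prototype(variants = data.frame(), traitLabel = "trait",
            traitType = "continuous",
            rejected = data.frame(variant_id = character(),
                                  reason = character())))

setValidity("AssociationTable", function(object) {
  v <- object@variants
  msgs <- character()
  missing_cols <- setdiff(.ASSOC_COLS, names(v))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (!object@traitType %in% c("binary", "continuous"))
    msgs <- c(msgs, "traitType must be 'binary' or 'continuous'")
  if (anyDuplicated(v$variant_id))
    msgs <- c(msgs, "variant_id must be unique")
  if (nrow(v)) {
    if (!all(v$effect_allele %in% .BASES) || !all(v$other_allele %in% .BASES))
      msgs <- c(msgs, "alleles must be single bases in {A,C,G,T}")
    if (any(v$effect_allele == v$other_allele))
      msgs <- c(msgs, "effect_allele must differ from other_allele")
    bad_eaf <- !is.na(v$eaf) & (v$eaf <= 0 | v$eaf >= 1)
    if (any(bad_eaf)) msgs <- c(msgs, "eaf must lie strictly in (0, 1)")
    if (any(!is.finite(v$se) | v$se <= 0)) msgs <- c(msgs, "se must be > 0")
    if (any(!is.finite(v$pval) | v$pval <= 0 | v$pval > 1))
      msgs <- c(msgs, "pval must lie in (0, 1]")
    if (any(!is.na(v$n) & v$n < 2)) msgs <- c(msgs, "n must be >= 2")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' LDMatrix: squared-correlation matrix between variants
#'
#' A square symmetric matrix of pairwise squared allelic correlations
#' (r-squared) with unit diagonal, keyed by variant identifier through its
#' dimnames.
#'
#' @slot r2 numeric matrix, symmetric, diagonal 1, entries in \[0, 1\],
#'   identical row and column names.
#' @export
setClass("LDMatrix", representation(r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  if (nrow(m) != ncol(m)) return("r2 must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    return("r2 must carry identical row and column variant labels")
  if (anyDuplicated(rownames(m))) return("variant labels must be unique")
  if (nrow(m) == 0) return(TRUE)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    return("entries must lie in [0, 1]")
  if (max(abs(m - t(m))) > 1e-12) return("r2 must be symmetric within 1e-12")
  if (any(diag(m) != 1)) return("diagonal must be exactly 1")
  TRUE
})

#' HarmonizedInstruments: exposure/outcome pairs on a shared effect allele
#'
#' The product of [harmonize()]: for every variant shared by the exposure and
#' outcome GWAS and resolvable to a common effect-allele orientation, both
#' sides' summary statistics expressed relative to the exposure's effect
#' allele, together with the per-SNP Wald ratio `beta_out / beta_exp` and its
#' first-order standard error `se_out / |beta_exp|`. Variants that could not
#' be harmonized sit in the exclusion log with a reason.
#'
#' @slot instruments data.frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `pval_exp`, `n_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `pval_out`, `n_out`, `wald_ratio`, `wald_se`.
#' @slot exclusions data.frame (`variant_id`, `reason`).
#' @slot exposureLabel,outcomeLabel trait names carried from the input tables.
#' @export
setClass("HarmonizedInstruments",
  representation(instruments = "data.frame", exclusions = "data.frame",
                 exposureLabel = "character", outcomeLabel = "character"),
  prototype(exclusions = data.frame(variant_id = character(),
                                    reason = character()),
            exposureLabel = "exposure", outcomeLabel = "outcome"))

setValidity("HarmonizedInstruments", function(object) {
  h <- object@instruments
  need <- c("variant_id", "effect_allele", "other_allele",
            "beta_exp", "se_exp", "eaf_exp", "pval_exp", "n_exp",
            "beta_out", "se_out", "eaf_out", "pval_out", "n_out",
            "wald_ratio", "wald_se")
  missing_cols <- setdiff(need, names(h))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(h)) {
    if (any(h$beta_exp == 0)) return("beta_exp must be non-zero")
    if (max(abs(h$wald_ratio - h$beta_out / h$beta_exp)) > 1e-12)
      return("wald_ratio must equal beta_out / beta_exp")
    if (max(abs(h$wald_se - h$se_out / abs(h$beta_exp))) > 1e-12)
      return("wald_se must equal se_out / |beta_exp|")
  }
  if (!all(c("variant_id", "reason") %in% names(object@exclusions)))
    return("exclusions must have variant_id and reason columns")
  TRUE
})

#' MREstimate: one causal-effect estimate
#'
#' One method's causal estimate on the log-odds (or standardized) scale,
#' with its odds-ratio transform and 95 percent confidence interval.
#'
#' @slot method one of `"MR-Egger"`, `"Weighted median"`, `"IVW"`,
#'   `"Simple mode"`, `"Weighted mode"`.
#' @slot b slope estimate; @slot se its standard error.
#' @slot or exp(b); @slot ciLow,ciHigh 95 percent CI of the odds ratio.
#' @slot pval two-sided p-value; @slot k number of instruments used.
#' @slot extras method-specific list (e.g. Egger intercept, Q statistic,
#'   bootstrap settings).
#' @export
setClass("MREstimate",
  representation(method = "character", b = "numeric", se = "numeric",
                 or = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 pval = "numeric", k = "integer", extras = "list"),
  prototype(extras = list()))

.MR_METHODS <- c("MR-Egger", "Weighted median", "IVW", "Simple mode",
                 "Weighted mode")

setValidity("MREstimate", function(object) {
  if (!object@method %in% .MR_METHODS)
    return(paste("method must be one of:", paste(.MR_METHODS, collapse = ", ")))
  if (abs(object@or - exp(object@b)) > 1e-12)
    return("or must equal exp(b) within 1e-12")
  if (is.finite(object@se) && object@se > 0 &&
      !(object@ciLow < object@or && object@or < object@ciHigh))
    return("ciLow < or < ciHigh must hold when se > 0")
  kmin <- if (object@method == "IVW") 2L else 3L
  if (object@k < kmin)
    return(sprintf("%s needs at least %d instruments", object@method, kmin))
  TRUE
})

#' SensitivityReport: heterogeneity, pleiotropy and leave-one-out results
#'
#' @slot qIvw,qEgger named numeric `(Q, df, pval)`: Cochran's Q about the
#'   fixed-effect IVW line (df = k - 1) and the Egger line (df = k - 2).
#' @slot eggerIntercept named numeric `(estimate, se, pval)`.
#' @slot loo data.frame with k + 1 rows (`variant_id`, `b`, `se`, `pval`),
#'   one per left-out variant plus an `"All"` row.
#' @slot alpha test level used for verdicts.
#' @export
setClass("SensitivityReport",
  representation(qIvw = "numeric", qEgger = "numeric",
                 eggerIntercept = "numeric", loo = "data.frame",
                 alpha = "numeric"),
  prototype(alpha = 0.05))

setValidity("SensitivityReport", function(object) {
  for (q in list(object@qIvw, object@qEgger)) {
    if (!all(c("Q", "df", "pval") %in% names(q)))
      return("Q slots must be named (Q, df, pval)")
    if (q[["Q"]] < 0) return("Q must be >= 0")
    if (q[["pval"]] <= 0 || q[["pval"]] > 1) return("Q p-value must lie in (0, 1]")
  }
  if (!all(c("estimate", "se", "pval") %in% names(object@eggerIntercept)))
    return("eggerIntercept must be named (estimate, se, pval)")
  if (!"All" %in% object@loo$variant_id)
    return("loo must contain an 'All' row")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must lie in (0, 1)")
  TRUE
})
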