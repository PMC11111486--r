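#' Instrument-screening configuration
#'
#' Thresholds for the five instrument-screening criteria: genome-wide
#' significance, LD clumping, minor-allele-frequency filter, per-SNP
#' F-statistic filter and Steiger directionality filter.
#'
#' @slot pvalThreshold exposure p-value ceiling (default `5e-8`,
#'   genome-wide significance).
#' @slot clumpR2 r-squared ceiling for clumping (default `0.001`).
#' @slot clumpKb clumping distance window in kilobases (default `10000`).
#' @slot mafMin minimum minor-allele frequency (default `0.01`).
#' @slot fMin minimum per-SNP F-statistic (default `10`, the conventional
#'   weak-instrument cutoff).
#' @slot steiger whether the Steiger directionality filter runs (default on).
#' @export
setClass("SelectionConfig",
  representation(pvalThreshold = "numeric", clumpR2 = "numeric",
                 clumpKb = "numeric", mafMin = "numeric", fMin = "numeric",
                 steiger = "logical"))

setValidity("SelectionConfig", function(object) {
  if (object@pvalThreshold <= 0 || object@mafMin <= 0 || object@fMin <= 0 ||
      object@clumpKb <= 0)
    return("all thresholds must be strictly positive")
  if (object@clumpR2 <= 0 || object@clumpR2 >= 1)
    return("clumpR2 must lie in (0, 1)")
  TRUE
})

#' @rdname SelectionConfig-class
#' @param pvalThreshold,clumpR2,clumpKb,mafMin,fMin,steiger see slots.
#' @return `SelectionConfig()` returns a validated configuration object.
#' @export
SelectionConfig <- function(pvalThreshold = 5e-8, clumpR2 = 0.001,
                            clumpKb = 10000, mafMin = 0.01, fMin = 10,
                            steiger = TRUE) {
  new("SelectionConfig", pvalThreshold = pvalThreshold, clumpR2 = clumpR2,
      clumpKb = clumpKb, mafMin = mafMin, fMin = fMin, steiger = steiger)
}

.lookupR2 <- function(ld, id_a, id_b, strict) {
  if (is.null(ld)) return(0)
  m <- ld@r2
  ok_a <- id_a %in% rownames(m); ok_b <- id_b %in% rownames(m)
  if (!ok_a || !ok_b) {
    if (strict)
      mrStop("mr_unknown_variant_ld",
             paste("variant missing from LD matrix:",
                   if (!ok_a) id_a else id_b))
    return(0)
  }
  m[id_a, id_b]
}

#' Greedy LD clumping by p-value priority
#'
#' Sorts variants by ascending p-value (ties broken by chromosome label then
#' position) and repeatedly keeps the best remaining variant, removing every
#' remaining variant that is both within `clumpKb` kilobases of it on the
#' same chromosome and correlated with it at `r2 >= clumpR2`. Variants on
#' other chromosomes, or farther away than the window, are never removed by
#' that index variant regardless of the supplied r-squared. With no LD matrix
#' all pairwise r-squared values are taken as zero and a warning is issued.
#'
#' @param table an [AssociationTable-class].
#' @param ld an [LDMatrix-class], or `NULL`.
#' @param clumpR2,clumpKb clumping thresholds; see [SelectionConfig()].
#' @param strict if `TRUE`, a variant absent from the supplied LD matrix is
#'   an error rather than being treated as uncorrelated.
#' @return An [AssociationTable-class] holding the retained variants in
#'   p-value order.
#' @export
ldClump <- function(table, ld = NULL, clumpR2 = 0.001, clumpKb = 10000,
                    strict = FALSE) {
  stopifnot(is(table, "AssociationTable"))
  v <- table@variants
  if (nrow(v) == 0L) mrStop("mr_empty_table", "cannot clump an empty table")
  if (is.null(ld))
    warning("no LD matrix supplied: all pairwise r-squared treated as 0",
            call. = FALSE)
  ord <- order(v$pval, v$chromosome, v$position, na.last = TRUE)
  v <- v[ord, , drop = FALSE]
  window_bp <- clumpKb * 1000
  keep <- logical(nrow(v))
  alive <- rep(TRUE, nrow(v))
  for (i in seq_len(nrow(v))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    others <- which(alive)
    for (j in others) {
      same_chr <- !is.na(v$chromosome[i]) && !is.na(v$chromosome[j]) &&
        v$chromosome[i] == v$chromosome[j]
      near <- same_chr && !is.na(v$position[i]) && !is.na(v$position[j]) &&
        abs(v$position[i] - v$position[j]) <= window_bp
      if (near &&
          .lookupR2(ld, v$variant_id[i], v$variant_id[j], strict) >= clumpR2)
        alive[j] <- FALSE
    }
  }
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  initialize(table, variants = out)
}

# Variance explained by one SNP under the standard bi-allelic approximation.
.varianceExplained <- function(eaf, beta) 2 * eaf * (1 - eaf) * beta^2

#' Per-SNP variance explained and F-statistic
#'
#' For each variant computes the variance explained
#' `R2 = 2 * EAF * (1 - EAF) * beta^2` and the instrument-strength
#' F-statistic `F = R2 * (N - 2) / (1 - R2)`, each with that SNP's own sample
#' size. `F < 10` conventionally flags a weak instrument.
#'
#' @param table an [AssociationTable-class]; `eaf` and `n` must be present
#'   for every row.
#' @return data.frame (`variant_id`, `r2`, `f_stat`).
#' @export
computeFStatistics <- function(table) {
  stopifnot(is(table, "AssociationTable"))
  v <- table@variants
  if (any(is.na(v$eaf)))
    mrStop("mr_missing_field", "eaf is required for every variant",
           field = "eaf")
  if (any(is.na(v$n)))
    mrStop("mr_missing_field", "n is required for every variant", field = "n")
  r2 <- .varianceExplained(v$eaf, v$beta)
  data.frame(variant_id = v$variant_id, r2 = r2,
             f_stat = r2 * (v$n - 2) / (1 - r2), stringsAsFactors = FALSE)
}

#' Steiger directionality filter
#'
#' Per instrument, compares the variance explained in the exposure against
#' the variance explained in the outcome, both via
#' `2 * EAF * (1 - EAF) * beta^2` on each side's own frequency and effect. A
#' variant is retained only when it explains strictly more variance in the
#' exposure (`exposure_to_outcome` direction); ties are dropped as
#' `ambiguous`, larger outcome variance as reverse causation. The shared
#' variance-explained approximation is applied to binary traits on the
#' log-odds scale as well; supply `r2Exposure` / `r2Outcome` to override it
#' with externally computed values.
#'
#' @param object a [HarmonizedInstruments-class]; both sides need `eaf`.
#' @param r2Exposure,r2Outcome optional numeric vectors (one value per
#'   instrument) replacing the built-in variance-explained formula.
#' @return list with elements `instruments` (filtered
#'   [HarmonizedInstruments-class], exclusion log extended) and
#'   `diagnostics` (data.frame `variant_id`, `r2_exposure`, `r2_outcome`,
#'   `steiger_direction`).
#' @export
steigerFilter <- function(object, r2Exposure = NULL, r2Outcome = NULL) {
  stopifnot(is(object, "HarmonizedInstruments"))
  h <- object@instruments
  if (is.null(r2Exposure)) {
    if (any(is.na(h$eaf_exp)) || any(is.na(h$eaf_out)))
      mrStop("mr_missing_field",
             "eaf is required on both sides for the Steiger filter",
             field = "eaf")
    r2Exposure <- .varianceExplained(h$eaf_exp, h$beta_exp)
    r2Outcome <- .varianceExplained(h$eaf_out, h$beta_out)
  }
  direction <- ifelse(r2Exposure > r2Outcome, "exposure_to_outcome",
                      ifelse(r2Exposure < r2Outcome, "outcome_to_exposure",
                             "ambiguous"))
  diagnostics <- data.frame(variant_id = h$variant_id,
                            r2_exposure = r2Exposure,
                            r2_outcome = r2Outcome,
                            steiger_direction = direction,
                            stringsAsFactors = FALSE)
  keep <- direction == "exposure_to_outcome"
  dropped <- data.frame(
    variant_id = h$variant_id[!keep],
    reason = ifelse(direction[!keep] == "ambiguous", "steiger-ambiguous",
                    "steiger-reverse"),
    stringsAsFactors = FALSE)
  kept <- initialize(object, instruments = {
    x <- h[keep, , drop = FALSE]; rownames(x) <- NULL; x
  }, exclusions = rbind(object@exclusions, dropped))
  list(instruments = kept, diagnostics = diagnostics)
}

#' Run the full instrument-selection pipeline
#'
#' Applies, in order: the exposure p-value threshold, the minor-allele-
#' frequency filter, LD clumping, harmonization against the outcome, the
#' per-SNP F-statistic filter and (optionally) the Steiger directionality
#' filter. An audit trail records, per stage, the counts in and out and the
#' identifiers removed; counts telescope so that input size equals output
#' size plus total removals. Variants with missing allele frequency pass the
#' MAF stage unassessed but make the F stage fail loudly.
#'
#' @param exposure,outcome [AssociationTable-class] objects.
#' @param ld optional [LDMatrix-class] for clumping.
#' @param config a [SelectionConfig()].
#' @param strictLd passed to [ldClump()] as `strict`.
#' @return list: `instruments` ([HarmonizedInstruments-class]),
#'   `diagnostics` (per retained instrument: variance explained on both
#'   sides, F-statistic, Steiger direction), `audit` (data.frame `stage`,
#'   `n_in`, `n_removed`, `n_out`, `removed`).
#' @export
selectInstruments <- function(exposure, outcome, ld = NULL,
                              config = SelectionConfig(), strictLd = FALSE) {
  stopifnot(is(exposure, "AssociationTable"),
            is(outcome, "AssociationTable"), is(config, "SelectionConfig"))
  audit <- list()
  note <- function(stage, before_ids, after_ids) {
    removed <- setdiff(before_ids, after_ids)
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = stage, n_in = length(before_ids), n_removed = length(removed),
      n_out = length(after_ids),
      removed = paste(removed, collapse = ","), stringsAsFactors = FALSE)
    if (length(after_ids) == 0L)
      mrStop("mr_empty_selection",
             sprintf("no instruments survived stage '%s'", stage),
             stage = stage, audit = do.call(rbind, audit))
  }

  tab <- exposure
  ids0 <- tab@variants$variant_id
  keep <- tab@variants$pval < config@pvalThreshold
  tab <- initialize(tab, variants = tab@variants[keep, , drop = FALSE])
  note("pvalue", ids0, tab@variants$variant_id)

  ids1 <- tab@variants$variant_id
  maf <- pmin(tab@variants$eaf, 1 - tab@variants$eaf)
  keep <- is.na(maf) | maf >= config@mafMin
  tab <- initialize(tab, variants = tab@variants[keep, , drop = FALSE])
  note("maf", ids1, tab@variants$variant_id)

  ids2 <- tab@variants$variant_id
  tab <- ldClump(tab, ld = ld, clumpR2 = config@clumpR2,
                 clumpKb = config@clumpKb, strict = strictLd)
  note("clump", ids2, tab@variants$variant_id)

  ids3 <- tab@variants$variant_id
  harm <- harmonize(tab, outcome)
  note("harmonize", ids3, harm@instruments$variant_id)

  ids4 <- harm@instruments$variant_id
  fstats <- computeFStatistics(initialize(tab, variants = {
    h <- harm@instruments
    data.frame(variant_id = h$variant_id, chromosome = h$chromosome,
               position = h$position, effect_allele = h$effect_allele,
               other_allele = h$other_allele, eaf = h$eaf_exp,
               beta = h$beta_exp, se = h$se_exp, pval = h$pval_exp,
               n = h$n_exp, stringsAsFactors = FALSE)
  }))
  keep <- fstats$f_stat >= config@fMin
  weak <- data.frame(variant_id = fstats$variant_id[!keep],
                     reason = rep("weak-instrument", sum(!keep)),
                     stringsAsFactors = FALSE)
  harm <- initialize(harm, instruments = {
    x <- harm@instruments[keep, , drop = FALSE]; rownames(x) <- NULL; x
  }, exclusions = rbind(harm@exclusions, weak))
  note("fstat", ids4, harm@instruments$variant_id)

  diagnostics <- data.frame(variant_id = fstats$variant_id,
                            r2_exposure = fstats$r2,
                            r2_outcome = NA_real_,
                            f_stat = fstats$f_stat,
                            steiger_direction = NA_character_,
                            stringsAsFactors = FALSE)
  if (config@steiger) {
    ids5 <- harm@instruments$variant_id
    st <- steigerFilter(harm)
    harm <- st$instruments
    note("steiger", ids5, harm@instruments$variant_id)
    m <- match(st$diagnostics$variant_id, diagnostics$variant_id)
    diagnostics$r2_outcome[m] <- st$diagnostics$r2_outcome
    diagnostics$steiger_direction[m] <- st$diagnostics$steiger_direction
  }
  diagnostics <- diagnostics[diagnostics$variant_id %in%
                               harm@instruments$variant_id, , drop = FALSE]
  rownames(diagnostics) <- NULL
  list(instruments = harm, diagnostics = diagnostics,
       audit = do.call(rbind, audit))
}
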