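#' Per-SNP Wald ratios
#'
#' The elementary per-instrument causal estimate all aggregate methods build
#' on: outcome effect divided by exposure effect, with the first-order
#' standard error `se_out / |beta_exp|` that ignores exposure-side sampling
#' noise (second-order for genome-wide-significant instruments). Set
#' `secondOrder = TRUE` for the variant that propagates exposure noise.
#'
#' @param object a [HarmonizedInstruments-class] with at least one
#'   instrument; all `beta_exp` non-zero.
#' @param secondOrder if `TRUE`, the SE adds the exposure-noise term:
#'   `sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#' @return data.frame (`variant_id`, `ratio`, `se`).
#' @export
waldRatios <- function(object, secondOrder = FALSE) {
  .assertInstruments(object, 1L, "waldRatios")
  h <- object@instruments
  if (any(h$beta_exp == 0))
    mrStop("mr_zero_exposure_effect", "beta_exp must be non-zero")
  se <- if (secondOrder)
    sqrt(h$se_out^2 / h$beta_exp^2 +
           h$beta_out^2 * h$se_exp^2 / h$beta_exp^4)
  else h$se_out / abs(h$beta_exp)
  data.frame(variant_id = h$variant_id, ratio = h$beta_out / h$beta_exp,
             se = se, stringsAsFactors = FALSE)
}

#' Log-odds to odds-ratio transform
#'
#' @param b slope on the log-odds scale.
#' @param se its standard error (`>= 0`).
#' @return named numeric `(or, ci_low, ci_high)` with
#'   `or = exp(b)` and the 95 percent interval `exp(b -/+ 1.959964 * se)`.
#' @export
toOddsRatio <- function(b, se) {
  stopifnot(is.finite(b), se >= 0)
  c(or = exp(b), ci_low = exp(b - .Z975 * se), ci_high = exp(b + .Z975 * se))
}

# Fixed-effect IVW slope and components, shared by the estimator and
# Cochran's Q.
.ivwFit <- function(h) {
  w <- 1 / h$se_out^2
  b <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  se_fixed <- sqrt(1 / sum(w * h$beta_exp^2))
  Q <- sum(w * (h$beta_out - b * h$beta_exp)^2)
  list(b = b, se_fixed = se_fixed, Q = Q)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1 / se_out^2` — algebraically the inverse-variance-
#' weighted mean of the Wald ratios. The fixed-effect standard error is
#' `(sum w beta_exp^2)^(-1/2)`; the multiplicative random-effects model (the
#' default) inflates it by `sqrt(max(1, Q / (k - 1)))`, so it can never be
#' anti-conservative and coincides with the fixed-effect SE when Cochran's Q
#' does not exceed its degrees of freedom. P-values are two-sided normal.
#'
#' @param object a [HarmonizedInstruments-class] with `k >= 2`.
#' @param effectsModel `"multiplicative_random"` (default) or `"fixed"`.
#' @return An [MREstimate-class]; `extras` carries `Q`, `seFixed`,
#'   `seRandom` and the model used.
#' @export
mrIVW <- function(object, effectsModel = c("multiplicative_random", "fixed")) {
  effectsModel <- match.arg(effectsModel)
  k <- .assertInstruments(object, 2L, "IVW")
  fit <- .ivwFit(object@instruments)
  se_random <- fit$se_fixed * sqrt(max(1, fit$Q / (k - 1)))
  se <- if (effectsModel == "fixed") fit$se_fixed else se_random
  .newEstimate("IVW", fit$b, se, 2 * stats::pnorm(-abs(fit$b / se)), k,
               extras = list(Q = fit$Q, seFixed = fit$se_fixed,
                             seRandom = se_random,
                             effectsModel = effectsModel))
}

#' MR-Egger regression
#'
#' Orients every instrument to a non-negative exposure effect (negating both
#' sides where needed — the estimate is invariant to the input orientation),
#' then fits a weighted linear regression of outcome on exposure effects with
#' a free intercept and weights `1 / se_out^2`. The intercept estimates the
#' average directional pleiotropy; the slope is the causal estimate under the
#' InSIDE assumption. Standard errors are scaled by
#' `sqrt(max(1, Q_egger / (k - 2)))` and p-values use the t distribution with
#' `k - 2` degrees of freedom.
#'
#' @param object a [HarmonizedInstruments-class] with `k >= 3` and
#'   non-constant oriented exposure effects.
#' @return An [MREstimate-class] for the slope; `extras` carries
#'   `intercept`, `interceptSE`, `interceptP`, `Q` (Egger residual Q) and
#'   `exactFit` (`TRUE` when the residual Q is numerically zero).
#' @export
mrEgger <- function(object) {
  k <- .assertInstruments(object, 3L, "MR-Egger")
  h <- object@instruments
  flip <- ifelse(h$beta_exp < 0, -1, 1)
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  if (diff(range(bx)) < 1e-12)
    mrStop("mr_collinear_design",
           "exposure effects are all equal after orientation")
  w <- 1 / h$se_out^2
  # centered weighted least squares: numerically stable closed form
  W <- sum(w)
  xbar <- sum(w * bx) / W
  ybar <- sum(w * by) / W
  sxx <- sum(w * (bx - xbar)^2)
  slope <- sum(w * (bx - xbar) * (by - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- by - intercept - slope * bx
  Q <- sum(w * resid^2)
  scale <- max(1, Q / (k - 2))
  ses <- sqrt(c(intercept = (1 / W + xbar^2 / sxx), slope = 1 / sxx) * scale)
  coefs <- c(intercept = intercept, slope = slope)
  pvals <- 2 * stats::pt(-abs(coefs / ses), df = k - 2)
  .newEstimate("MR-Egger", coefs[["slope"]], ses[["slope"]],
               pvals[["slope"]], k,
               extras = list(intercept = coefs[["intercept"]],
                             interceptSE = ses[["intercept"]],
                             interceptP = pvals[["intercept"]],
                             Q = Q, exactFit = Q < 1e-12))
}

.weightedMedianPoint <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  wn <- weight[ord] / sum(weight)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap over both sides' betas; statistic() maps a
# (ratio, weight) pair to a scalar estimate.
.ratioBootstrap <- function(h, statistic, nBoot, seed) {
  withSeed(seed, {
    reps <- vapply(seq_len(nBoot), function(i) {
      bx <- stats::rnorm(nrow(h), h$beta_exp, h$se_exp)
      by <- stats::rnorm(nrow(h), h$beta_out, h$se_out)
      bx[bx == 0] <- .Machine$double.eps
      statistic(by / bx, (abs(bx) / h$se_out)^2)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimator
#'
#' The weighted median of the per-SNP Wald ratios with normalized
#' inverse-variance weights: ratios are sorted, breakpoints
#' `s_j = (cumulative weight up to j) - w_j / 2` computed, and the estimate
#' linearly interpolated at `s = 0.5`. Consistent when at least half the
#' total weight comes from valid instruments. The standard error is the
#' standard deviation of the estimator over `nBoot` parametric-bootstrap
#' replicates in which both sides' betas are re-drawn from normals with their
#' reported SEs; the p-value is two-sided normal.
#'
#' @param object a [HarmonizedInstruments-class] with `k >= 3`.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap, mandatory for reproducibility.
#' @return An [MREstimate-class]; `extras` carries `nBoot` and `seed`.
#' @export
mrWeightedMedian <- function(object, nBoot = 1000, seed) {
  k <- .assertInstruments(object, 3L, "weighted median")
  h <- object@instruments
  wr <- waldRatios(object)
  b <- .weightedMedianPoint(wr$ratio, 1 / wr$se^2)
  se <- .ratioBootstrap(h, function(r, w) .weightedMedianPoint(r, w),
                        nBoot, seed)
  .newEstimate("Weighted median", b, se, 2 * stats::pnorm(-abs(b / se)), k,
               extras = list(nBoot = nBoot, seed = seed))
}

.modePoint <- function(ratio, weight, phi) {
  wn <- weight / sum(weight)
  spread <- min(stats::sd(ratio), stats::mad(ratio))
  h <- phi * 0.9 * spread * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    rng <- diff(range(ratio))
    h <- if (rng > 0) rng / 100 else max(abs(ratio[1]), 1) * 1e-6
  }
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512L)
  dens <- colSums(wn * outer(ratio, grid,
                             function(r, g) stats::dnorm((g - r) / h))) / h
  grid[which.max(dens)]  # ascending grid: first maximum is the smallest value
}

#' Mode-based estimators (simple and weighted)
#'
#' Estimates the causal effect as the mode of the smoothed empirical density
#' of the Wald ratios: a normal-kernel density with bandwidth
#' `phi * 0.9 * min(SD, MAD) * k^(-1/5)` (MAD scaled to be consistent for
#' the normal SD) is evaluated on a 512-point uniform grid spanning the ratio
#' range extended by three bandwidths, and the estimate is the grid argmax
#' (ties resolved to the smallest value). The simple mode weighs every ratio
#' equally; the weighted mode uses normalized inverse-variance weights.
#' Standard errors come from the same parametric bootstrap as the weighted
#' median.
#'
#' @param object a [HarmonizedInstruments-class] with `k >= 3`.
#' @param weighted `TRUE` for the weighted mode, `FALSE` for the simple mode.
#' @param phi bandwidth multiplier (default 1).
#' @param nBoot,seed bootstrap settings, as in [mrWeightedMedian()].
#' @return An [MREstimate-class]; `extras` carries `phi`, `nBoot`, `seed`.
#' @export
mrMode <- function(object, weighted = FALSE, phi = 1, nBoot = 1000, seed) {
  k <- .assertInstruments(object, 3L, "mode estimator")
  h <- object@instruments
  wr <- waldRatios(object)
  wfun <- if (weighted) function(r, w) w else function(r, w) rep(1, length(r))
  b <- .modePoint(wr$ratio, wfun(wr$ratio, 1 / wr$se^2), phi)
  se <- .ratioBootstrap(h, function(r, w) .modePoint(r, wfun(r, w), phi),
                        nBoot, seed)
  .newEstimate(if (weighted) "Weighted mode" else "Simple mode", b, se,
               2 * stats::pnorm(-abs(b / se)), k,
               extras = list(phi = phi, nBoot = nBoot, seed = seed))
}

#' Run all five causal estimators
#'
#' Computes MR-Egger, weighted median, IVW, simple mode and weighted mode on
#' one instrument set, threading a shared seed through the bootstrap-based
#' methods (offset per method so replicates are independent but the whole
#' report is reproducible bit for bit).
#'
#' @param object a [HarmonizedInstruments-class] with `k >= 3`.
#' @param effectsModel IVW variant, see [mrIVW()].
#' @param nBoot,phi,seed estimator settings.
#' @return Named list of five [MREstimate-class] objects in the order
#'   `MR-Egger`, `Weighted median`, `IVW`, `Simple mode`, `Weighted mode`.
#' @export
runAllMethods <- function(object, effectsModel = c("multiplicative_random",
                                                   "fixed"),
                          nBoot = 1000, phi = 1, seed) {
  effectsModel <- match.arg(effectsModel)
  .assertInstruments(object, 3L, "runAllMethods")
  if (missing(seed)) mrStop("mr_invalid_config", "seed is required")
  out <- list(
    "MR-Egger" = mrEgger(object),
    "Weighted median" = mrWeightedMedian(object, nBoot = nBoot, seed = seed),
    "IVW" = mrIVW(object, effectsModel = effectsModel),
    "Simple mode" = mrMode(object, weighted = FALSE, phi = phi,
                           nBoot = nBoot, seed = seed + 1L),
    "Weighted mode" = mrMode(object, weighted = TRUE, phi = phi,
                             nBoot = nBoot, seed = seed + 2L))
  out
}

#' Tabulate a list of MREstimate objects
#'
#' @param estimates a (named) list of [MREstimate-class] objects, e.g. from
#'   [runAllMethods()].
#' @param type optional label prepended as a `type` column (trait or
#'   subtype name).
#' @return data.frame with columns `method`, `b`, `se`, `or`, `ci_low`,
#'   `ci_high`, `pval`, `k` (plus `type` when given).
#' @export
estimatesTable <- function(estimates, type = NULL) {
  rows <- lapply(estimates, function(e) {
    data.frame(method = e@method, b = e@b, se = e@se, or = e@or,
               ci_low = e@ciLow, ci_high = e@ciHigh, pval = e@pval,
               k = e@k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(type)) out <- cbind(type = type, out, stringsAsFactors = FALSE)
  out
}
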