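# Typed conditions. Every domain error signalled by the package carries the
# class "mrcausal_error" plus a specific subclass so callers can dispatch.
mrStop <- function(subclass, message, ...) {
  stop(structure(class = c(subclass, "mrcausal_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state so
# seeded helpers never perturb an enclosing simulation.
withSeed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    mrStop("mr_invalid_config", "a finite integer seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.complementBase <- function(x) {
  chartr("ACGT", "TGCA", x)
}

.isPalindromic <- function(a1, a2) {
  a2 == .complementBase(a1)
}

# z for a 95% interval, fixed to six significant figures so odds-ratio CIs
# are reproducible across platforms.
.Z975 <- 1.959964

.assertInstruments <- function(object, kmin, what) {
  if (!is(object, "HarmonizedInstruments"))
    stop(what, " expects a HarmonizedInstruments object")
  k <- nrow(object@instruments)
  if (k < kmin)
    mrStop("mr_too_few_instruments",
           sprintf("%s needs at least %d instruments, got %d", what, kmin, k))
  invisible(k)
}

.newEstimate <- function(method, b, se, pval, k, extras = list()) {
  orci <- toOddsRatio(b, se)
  new("MREstimate", method = method, b = b, se = se, or = orci[["or"]],
      ciLow = orci[["ci_low"]], ciHigh = orci[["ci_high"]],
      pval = pval, k = as.integer(k), extras = extras)
}
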