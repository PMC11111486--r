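#' Simulation configuration for two-sample GWAS summary statistics
#'
#' Defines the generating model: `k` independent instruments with minor
#' allele frequencies uniform on `mafRange`; true exposure effects of
#' magnitude uniform on `gammaRange` with random sign (the sign encodes which
#' allele is effect-coded); a fraction `propInvalid` of instruments carrying
#' a direct (pleiotropic) outcome effect drawn from
#' `Normal(muAlpha, sdAlpha^2)` and applied on the exposure-increasing
#' allele; true outcome effects `betaTrue * gamma + pleiotropy`; and
#' independent sampling noise on the two sides with standard errors
#' `(2 p (1 - p) N)^(-1/2)` on the standardized scale. Defaults mirror a
#' stroke-scale exposure GWAS (N = 40,585) against a frailty-index-scale
#' outcome GWAS (N = 175,226).
#'
#' @slot k number of instruments (`>= 1`).
#' @slot betaTrue causal effect of exposure on outcome.
#' @slot nExp,nOut per-SNP sample sizes of the two GWAS.
#' @slot mafRange,gammaRange ordered ranges, see above.
#' @slot propInvalid fraction of instruments with pleiotropy, in \[0, 1\].
#' @slot muAlpha,sdAlpha pleiotropy mean and SD (directional when
#'   `muAlpha != 0`, balanced when `muAlpha = 0, sdAlpha > 0`).
#' @slot ldBlocks list of `c(size, r)` pairs describing correlated blocks
#'   (used by [ldBlockFixture()]); empty for independent instruments.
#' @slot palindromicFraction fraction of variants assigned A/T or G/C
#'   allele pairs (default 0: all pairs strand-resolvable).
#' @slot seed integer seed, mandatory.
#' @export
setClass("SimulationConfig",
  representation(k = "integer", betaTrue = "numeric", nExp = "integer",
                 nOut = "integer", mafRange = "numeric",
                 gammaRange = "numeric", propInvalid = "numeric",
                 muAlpha = "numeric", sdAlpha = "numeric", ldBlocks = "list",
                 palindromicFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (object@nExp < 2L || object@nOut < 2L) return("sample sizes must be >= 2")
  for (rng in list(object@mafRange, object@gammaRange))
    if (length(rng) != 2L || rng[1] > rng[2]) return("ranges must be ordered pairs")
  if (object@mafRange[1] <= 0 || object@mafRange[2] > 0.5)
    return("mafRange must lie in (0, 0.5]")
  if (object@propInvalid < 0 || object@propInvalid > 1)
    return("propInvalid must lie in [0, 1]")
  if (object@sdAlpha < 0) return("sdAlpha must be >= 0")
  if (object@palindromicFraction < 0 || object@palindromicFraction > 1)
    return("palindromicFraction must lie in [0, 1]")
  for (blk in object@ldBlocks) {
    if (length(blk) != 2L) return("each LD block must be c(size, r)")
    if (blk[1] < 2L) return("LD block size must be >= 2")
    if (abs(blk[2]) >= 1) return("LD block |r| must be < 1")
  }
  if (sum(vapply(object@ldBlocks, `[`, numeric(1), 1L)) > object@k)
    return("LD blocks cannot exceed k variants")
  if (!length(object@seed)) return("seed is mandatory")
  TRUE
})

#' @rdname SimulationConfig-class
#' @param k,betaTrue,nExp,nOut,mafRange,gammaRange,propInvalid,muAlpha,sdAlpha,ldBlocks,palindromicFraction,seed
#'   see slots.
#' @return `SimulationConfig()` returns a validated configuration.
#' @export
SimulationConfig <- function(k, betaTrue, nExp = 40585L, nOut = 175226L,
                             mafRange = c(0.05, 0.5),
                             gammaRange = c(0.05, 0.15), propInvalid = 0,
                             muAlpha = 0, sdAlpha = 0, ldBlocks = list(),
                             palindromicFraction = 0, seed) {
  if (missing(seed)) mrStop("mr_invalid_config", "seed is mandatory")
  tryCatch(
    new("SimulationConfig", k = as.integer(k), betaTrue = betaTrue,
        nExp = as.integer(nExp), nOut = as.integer(nOut),
        mafRange = mafRange, gammaRange = gammaRange,
        propInvalid = propInvalid, muAlpha = muAlpha, sdAlpha = sdAlpha,
        ldBlocks = ldBlocks, palindromicFraction = palindromicFraction,
        seed = as.integer(seed)),
    error = function(e) mrStop("mr_invalid_config", conditionMessage(e)))
}

.NONPAL_PAIRS <- matrix(c("A", "G", "G", "A", "A", "C", "C", "A",
                          "T", "G", "G", "T", "T", "C", "C", "T"),
                        ncol = 2L, byrow = TRUE)
.PAL_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                     ncol = 2L, byrow = TRUE)

.assembleTables <- function(ids, chromosome, position, alleles, maf,
                            bx, se_x, by, se_y, cfg) {
  pval <- function(b, se) pmax(2 * stats::pnorm(-abs(b / se)),
                               .Machine$double.xmin)
  mk <- function(b, se, n, label, type)
    AssociationTable(data.frame(
      variant_id = ids, chromosome = chromosome, position = position,
      effect_allele = alleles[, 1L], other_allele = alleles[, 2L],
      eaf = maf, beta = b, se = se, pval = pval(b, se), n = n,
      stringsAsFactors = FALSE), traitLabel = label, traitType = type)
  list(exposure = mk(bx, se_x, cfg@nExp, "simulated exposure", "binary"),
       outcome = mk(by, se_y, cfg@nOut, "simulated outcome", "continuous"))
}

.drawAlleles <- function(k, palFraction) {
  pal <- stats::runif(k) < palFraction
  idx_np <- sample.int(nrow(.NONPAL_PAIRS), k, replace = TRUE)
  idx_p <- sample.int(nrow(.PAL_PAIRS), k, replace = TRUE)
  out <- .NONPAL_PAIRS[idx_np, , drop = FALSE]
  out[pal, ] <- .PAL_PAIRS[idx_p[pal], , drop = FALSE]
  out
}

.drawPleiotropy <- function(k, cfg) {
  invalid <- stats::runif(k) < cfg@propInvalid
  alpha <- ifelse(invalid, stats::rnorm(k, cfg@muAlpha, cfg@sdAlpha), 0)
  list(invalid = invalid, alpha = alpha)
}

#' Simulate independent two-sample GWAS summary statistics
#'
#' Draws per-SNP summary statistics for an exposure and an outcome GWAS from
#' the model described in [SimulationConfig-class], with the two samples'
#' estimation errors independent (the two-sample design). The latent truth —
#' per-SNP minor allele frequency, true exposure effect, pleiotropic effect,
#' true outcome effect and both sampling SEs — is returned alongside.
#'
#' @param config a [SimulationConfig()].
#' @return list: `exposure` and `outcome` ([AssociationTable-class]) and
#'   `truth` (list with `betaTrue` and the per-SNP data.frame `perSnp`).
#' @export
simulateTwoSample <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  withSeed(config@seed, {
    k <- config@k
    ids <- sprintf("snp%04d", seq_len(k))
    maf <- stats::runif(k, config@mafRange[1], config@mafRange[2])
    s <- sample(c(-1, 1), k, replace = TRUE)
    gamma <- s * stats::runif(k, config@gammaRange[1], config@gammaRange[2])
    pl <- .drawPleiotropy(k, config)
    Gamma <- config@betaTrue * gamma + s * pl$alpha
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config@nExp)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config@nOut)
    bx <- stats::rnorm(k, gamma, se_x)
    by <- stats::rnorm(k, Gamma, se_y)
    alleles <- .drawAlleles(k, config@palindromicFraction)
    tabs <- .assembleTables(ids, rep("1", k), seq_len(k) * 2e7, alleles, maf,
                            bx, se_x, by, se_y, config)
    truth <- data.frame(variant_id = ids, maf = maf, gamma = gamma,
                        alpha = pl$alpha, Gamma = Gamma,
                        invalid = pl$invalid, se_exp = se_x, se_out = se_y,
                        stringsAsFactors = FALSE)
    c(tabs, list(truth = list(betaTrue = config@betaTrue, perSnp = truth)))
  })
}

#' Simulate correlated instruments with a matching LD matrix
#'
#' Generates summary statistics as in [simulateTwoSample()] but with the
#' variants organized into LD blocks: within a block of size `m` and
#' correlation `r`, the first member is the causal tag and member `i` (at
#' in-block distance `d = i - 1`) has true marginal effect `r^d` times the
#' tag's effect; estimation errors within a block are drawn jointly with
#' correlation `r^|i-j|` on both sides. Block members share a minor allele
#' frequency, sit within 50 kb of each other, and appear in the emitted
#' [LDMatrix-class] with entries `(r^|i-j|)^2`. Variants beyond the blocks
#' (up to `k`) are independent. Intended to exercise the clumping stage.
#'
#' @param config a [SimulationConfig()] with a non-empty `ldBlocks`.
#' @return list: `exposure`, `outcome`, `ld` ([LDMatrix-class]), `truth`.
#' @export
ldBlockFixture <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  if (!length(config@ldBlocks))
    mrStop("mr_invalid_config", "ldBlocks must be non-empty")
  withSeed(config@seed, {
    k <- config@k
    sizes <- vapply(config@ldBlocks, `[`, numeric(1), 1L)
    rs <- vapply(config@ldBlocks, `[`, numeric(1), 2L)
    block_of <- rep(0L, k)  # 0 = independent singleton
    pos_in_block <- integer(k)
    idx <- 1L
    for (b in seq_along(sizes)) {
      block_of[idx:(idx + sizes[b] - 1L)] <- b
      pos_in_block[idx:(idx + sizes[b] - 1L)] <- seq_len(sizes[b])
      idx <- idx + sizes[b]
    }
    ids <- sprintf("snp%04d", seq_len(k))
    maf <- stats::runif(k, config@mafRange[1], config@mafRange[2])
    gamma <- sample(c(-1, 1), k, TRUE) *
      stats::runif(k, config@gammaRange[1], config@gammaRange[2])
    # block members inherit the tag's maf and a decayed copy of its effect
    for (b in seq_along(sizes)) {
      members <- which(block_of == b)
      maf[members] <- maf[members[1L]]
      gamma[members] <- rs[b]^(pos_in_block[members] - 1L) *
        gamma[members[1L]]
    }
    pl <- .drawPleiotropy(k, config)
    s <- sign(gamma)
    Gamma <- config@betaTrue * gamma + s * pl$alpha
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config@nExp)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config@nOut)

    r2 <- diag(k)
    dimnames(r2) <- list(ids, ids)
    corr <- diag(k)
    for (b in seq_along(sizes)) {
      members <- which(block_of == b)
      d <- abs(outer(pos_in_block[members], pos_in_block[members], "-"))
      corr[members, members] <- rs[b]^d
      r2[members, members] <- (rs[b]^d)^2
    }
    eps_x <- drop(MASS::mvrnorm(1L, mu = rep(0, k),
                                Sigma = diag(se_x) %*% corr %*% diag(se_x)))
    eps_y <- drop(MASS::mvrnorm(1L, mu = rep(0, k),
                                Sigma = diag(se_y) %*% corr %*% diag(se_y)))
    bx <- gamma + eps_x
    by <- Gamma + eps_y
    # blocks span < 50 kb internally; successive blocks/singletons sit 20 Mb apart
    position <- (cumsum(ifelse(pos_in_block <= 1L, 2e7, 0)) +
                   pos_in_block * 5e4)
    alleles <- .drawAlleles(k, config@palindromicFraction)
    tabs <- .assembleTables(ids, rep("1", k), position, alleles, maf,
                            bx, se_x, by, se_y, config)
    truth <- data.frame(variant_id = ids, maf = maf, gamma = gamma,
                        alpha = pl$alpha, Gamma = Gamma, block = block_of,
                        invalid = pl$invalid, se_exp = se_x, se_out = se_y,
                        stringsAsFactors = FALSE)
    c(tabs, list(ld = LDMatrix(r2),
                 truth = list(betaTrue = config@betaTrue, perSnp = truth)))
  })
}

#' Packaged ischemic-stroke instrument table
#'
#' The 18 genome-wide-significant ischemic-stroke variants reported by the
#' MEGASTROKE consortium GWAS (34,217 ischemic-stroke cases), shipped as a
#' plain-text fixture: effect and non-effect allele, effect-allele frequency,
#' log-odds effect size, standard error and p-value per variant, with
#' N = 34,217 attached to every row. The variant identifiers are stored as
#' opaque labels: in the source table the rsID and chromosome columns are
#' typeset run together, so the trailing digits of each label are an
#' unresolvable mixture of rsID and chromosome and the `chromosome` and
#' `position` fields are left `NA`.
#'
#' @return An [AssociationTable-class] with 18 records
#'   (`traitType = "binary"`).
#' @export
ischemicStrokeInstruments <- function() {
  path <- system.file("extdata", "ischemic_stroke_instruments.tsv",
                      package = "mrcausal", mustWork = TRUE)
  readSummaryStats(path, traitLabel = "ischemic stroke (MEGASTROKE)",
                   traitType = "binary")
}
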