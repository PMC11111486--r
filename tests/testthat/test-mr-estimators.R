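test_that("Wald ratios divide outcome by exposure effects", {
  h <- makeH(bx = 0.1, by = 0.05, seOut = 0.01)
  wr <- waldRatios(h)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.1)
  # sign invariance: negating both sides leaves the ratio unchanged
  h2 <- makeH(bx = -0.1, by = -0.05, seOut = 0.01)
  expect_equal(waldRatios(h2)$ratio, 0.5)
  # second-order SE adds the exposure-noise term
  h3 <- makeH(bx = 0.1, by = 0.05, seOut = 0.01, seExp = 0.02)
  expect_equal(waldRatios(h3, secondOrder = TRUE)$se,
               sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))
  expect_error(HarmonizedInstruments(data.frame(
    variant_id = "a", beta_exp = 0, se_exp = 0.01, beta_out = 0.1,
    se_out = 0.01)), class = "mr_zero_exposure_effect")
})

test_that("IVW reproduces the hand-computed two-SNP instance exactly", {
  h <- makeH(bx = c(1, 1), by = c(0.5, 1.0), seOut = c(0.1, 0.1))
  fixed <- mrIVW(h, effectsModel = "fixed")
  random <- mrIVW(h)
  expect_equal(fixed@b, 0.75)
  expect_equal(fixed@se, sqrt(1 / 200))        # 0.0707...
  expect_equal(fixed@extras$Q, 12.5)
  expect_equal(random@se, 0.25)                # fixed SE * sqrt(Q / (k - 1))
  expect_equal(random@b, fixed@b)
})

test_that("IVW degenerates correctly for identical and equal-weight SNPs", {
  h <- makeH(bx = c(0.2, 0.2, 0.2), by = c(0.06, 0.06, 0.06),
             seOut = rep(0.01, 3))
  e <- mrIVW(h)
  expect_equal(e@b, 0.3)
  expect_equal(e@extras$Q, 0)
  expect_equal(e@extras$seRandom, e@extras$seFixed)  # floor at 1
  # equal outcome SEs: IVW equals unweighted least squares through the origin
  set.seed(13)
  bx <- runif(5, 0.1, 0.3); by <- rnorm(5, 0.1 * bx, 0.01)
  h2 <- makeH(bx, by, seOut = rep(0.02, 5))
  expect_equal(mrIVW(h2)@b, sum(bx * by) / sum(bx^2))
  expect_error(mrIVW(makeH(0.1, 0.05, 0.01)),
               class = "mr_too_few_instruments")
})

test_that("IVW and Egger match a generic weighted-least-squares oracle", {
  set.seed(29)
  for (trial in 1:50) {
    k <- sample(3:6, 1)
    bx <- rnorm(k, 0.15, 0.05); bx[bx == 0] <- 0.1
    by <- rnorm(k, 0.1 * bx + 0.01, 0.02)
    se <- runif(k, 0.01, 0.05)
    h <- makeH(bx, by, seOut = se)
    w <- 1 / se^2
    ivw_fit <- lm(by ~ 0 + bx, weights = w)
    expect_equal(mrIVW(h)@b, unname(coef(ivw_fit)), tolerance = 1e-12)
    fl <- sign(bx)
    egger_fit <- lm(I(by * fl) ~ I(bx * fl), weights = w)
    eg <- mrEgger(h)
    expect_equal(eg@extras$intercept, unname(coef(egger_fit)[1]),
                 tolerance = 1e-12)
    expect_equal(eg@b, unname(coef(egger_fit)[2]), tolerance = 1e-12)
  }
})

test_that("Egger recovers an exact line and is orientation-invariant", {
  h <- makeH(bx = c(1, 2, 3), by = c(0.4, 0.7, 1.0), seOut = rep(0.1, 3))
  e <- mrEgger(h)
  expect_equal(e@b, 0.3)
  expect_equal(e@extras$intercept, 0.1)
  expect_equal(e@extras$Q, 0, tolerance = 1e-20)
  expect_true(e@extras$exactFit)

  # negating one instrument's pair leaves slope and intercept unchanged
  h2 <- makeH(bx = c(1, -2, 3), by = c(0.4, -0.7, 1.0), seOut = rep(0.1, 3))
  e2 <- mrEgger(h2)
  expect_equal(e2@b, e@b)
  expect_equal(e2@extras$intercept, e@extras$intercept)

  expect_error(mrEgger(makeH(c(1, 1, 1), c(0.4, 0.5, 0.6), rep(0.1, 3))),
               class = "mr_collinear_design")
  expect_error(mrEgger(makeH(c(1, 2), c(0.4, 0.7), rep(0.1, 2))),
               class = "mr_too_few_instruments")
})

test_that("weighted median interpolates breakpoints and respects weights", {
  # equal weights on ratios (1, 2, 3): breakpoints 1/6, 1/2, 5/6
  h <- makeH(bx = c(1, 1, 1) * 0.1, by = c(1, 2, 3) * 0.1,
             seOut = rep(0.01, 3))
  wm <- mrWeightedMedian(h, nBoot = 50, seed = 4)
  expect_equal(wm@b, 2)
  # one SNP holding almost all the weight dominates
  h2 <- makeH(bx = rep(0.1, 3), by = c(0.1, 0.2, 0.32),
              seOut = c(0.1, 0.1, 0.001))
  expect_equal(mrWeightedMedian(h2, nBoot = 50, seed = 4)@b, 3.2,
               tolerance = 0.05)
  # determinism: same seed, same bootstrap SE
  a <- mrWeightedMedian(h, nBoot = 200, seed = 11)
  b <- mrWeightedMedian(h, nBoot = 200, seed = 11)
  expect_identical(a@se, b@se)
  expect_error(mrWeightedMedian(makeH(c(1, 1), c(1, 1), c(0.1, 0.1)),
                                nBoot = 10, seed = 1),
               class = "mr_too_few_instruments")
})

test_that("weighted median stays inside the ratio range and matches IVW on equal ratios", {
  set.seed(37)
  for (trial in 1:25) {
    k <- sample(3:8, 1)
    bx <- runif(k, 0.05, 0.3)
    by <- rnorm(k, 0.1 * bx, 0.02)
    h <- makeH(bx, by, seOut = runif(k, 0.01, 0.05))
    wm <- mrWeightedMedian(h, nBoot = 10, seed = trial)
    r <- waldRatios(h)$ratio
    expect_gte(wm@b, min(r)); expect_lte(wm@b, max(r))
  }
  h_eq <- makeH(bx = c(0.1, 0.2, 0.4), by = 0.5 * c(0.1, 0.2, 0.4),
                seOut = c(0.01, 0.02, 0.03))
  expect_equal(mrWeightedMedian(h_eq, nBoot = 10, seed = 1)@b, mrIVW(h_eq)@b)
})

test_that("mode estimators find the dominant ratio cluster", {
  h <- makeH(bx = rep(0.1, 4), by = 0.1 * c(1, 1, 1, 5),
             seOut = rep(0.01, 4))
  sm <- mrMode(h, weighted = FALSE, nBoot = 30, seed = 2)
  r <- waldRatios(h)$ratio
  grid_step <- (diff(range(r)) + 6 * 1) / 511  # generous step bound
  expect_lt(abs(sm@b - 1), grid_step)

  # all ratios equal: mode sits on the common value
  h2 <- makeH(bx = rep(0.1, 3), by = rep(0.07, 3), seOut = rep(0.01, 3))
  expect_equal(mrMode(h2, nBoot = 30, seed = 3)@b, 0.7, tolerance = 1e-3)

  # weighted mode follows the majority-weight cluster
  h3 <- makeH(bx = rep(0.1, 5), by = 0.1 * c(1, 1, 5, 5, 5),
              seOut = rep(0.01, 5))
  wmode <- mrMode(h3, weighted = TRUE, nBoot = 30, seed = 4)
  expect_equal(wmode@b, 5, tolerance = 0.1)
  smode <- mrMode(h3, weighted = FALSE, nBoot = 30, seed = 4)
  expect_equal(smode@b, 5, tolerance = 0.1)
})

test_that("odds-ratio transform matches the reported stroke values", {
  orci <- toOddsRatio(0.099, 0.019)
  expect_equal(round(orci[["or"]], 3), 1.104)
  expect_equal(orci[["ci_low"]], 1.0637, tolerance = 1e-4)
  expect_equal(orci[["ci_high"]], 1.1459, tolerance = 1e-4)
  flat <- toOddsRatio(0, 0.1)
  expect_equal(flat[["or"]], 1)
  expect_equal(flat[["ci_low"]] * flat[["ci_high"]], 1)  # log-symmetric
})

test_that("scaling exposure effects by c scales every slope by 1/c", {
  set.seed(41)
  bx <- runif(5, 0.1, 0.3); by <- rnorm(5, 0.1 * bx + 0.02, 0.01)
  se <- runif(5, 0.01, 0.03)
  h1 <- makeH(bx, by, seOut = se)
  h2 <- makeH(3 * bx, by, seOut = se)
  expect_equal(mrIVW(h2)@b, mrIVW(h1)@b / 3)
  e1 <- mrEgger(h1); e2 <- mrEgger(h2)
  expect_equal(e2@b, e1@b / 3)
  expect_equal(e2@extras$intercept, e1@extras$intercept)  # intercept unscaled
  expect_equal(mrWeightedMedian(h2, nBoot = 10, seed = 5)@b,
               mrWeightedMedian(h1, nBoot = 10, seed = 5)@b / 3)
})

test_that("runAllMethods emits the five labelled estimates deterministically", {
  sim <- simulateTwoSample(SimulationConfig(k = 12, betaTrue = 0.1,
                                            seed = 100))
  h <- harmonize(sim$exposure, sim$outcome)
  res <- runAllMethods(h, nBoot = 100, seed = 8)
  expect_named(res, c("MR-Egger", "Weighted median", "IVW", "Simple mode",
                      "Weighted mode"))
  for (e in res) {
    expect_s4_class(e, "MREstimate")
    expect_equal(e@or, exp(e@b), tolerance = 1e-14)
  }
  res2 <- runAllMethods(h, nBoot = 100, seed = 8)
  expect_identical(estimatesTable(res), estimatesTable(res2))
  expect_error(runAllMethods(h, nBoot = 10), class = "mr_invalid_config")

  # a common Wald ratio: every method lands on it
  bxc <- c(0.1, 0.2, 0.3, 0.4)
  hc <- makeH(bx = bxc, by = 0.25 * bxc, seOut = rep(0.01, 4))
  resc <- runAllMethods(hc, nBoot = 30, seed = 9)
  for (e in resc) expect_equal(e@b, 0.25, tolerance = 1e-3)
})
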