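test_that("greedy clumping keeps the index SNP and prunes correlated neighbours", {
  tab <- makeTable(c("A", "B", "C"), beta = rep(0.1, 3), se = rep(0.01, 3),
                   pval = c(1e-10, 1e-9, 1e-8),
                   position = c(1e6, 1e6 + 5e4, 1e6 + 1e5))
  r2 <- diag(3); dimnames(r2) <- list(c("A", "B", "C"), c("A", "B", "C"))
  r2["A", "B"] <- r2["B", "A"] <- 0.5
  out <- ldClump(tab, LDMatrix(r2), clumpR2 = 0.001, clumpKb = 10000)
  expect_setequal(variantIds(out), c("A", "C"))
  expect_equal(variantIds(out)[1], "A")  # p-value order preserved
})

test_that("uncorrelated variants pass clumping unchanged, ordered by p", {
  tab <- makeTable(c("x", "y", "z"), beta = rep(0.1, 3), se = rep(0.01, 3),
                   pval = c(1e-8, 1e-10, 1e-9))
  r2 <- diag(3); dimnames(r2) <- list(c("x", "y", "z"), c("x", "y", "z"))
  out <- ldClump(tab, LDMatrix(r2))
  expect_equal(variantIds(out), c("y", "z", "x"))
})

test_that("the distance window overrides the LD matrix", {
  # 15,000 kb apart: outside the 10,000 kb window, both kept despite r2 = 0.9
  tab <- makeTable(c("A", "B"), beta = rep(0.1, 2), se = rep(0.01, 2),
                   pval = c(1e-10, 1e-9), position = c(1e6, 1e6 + 1.5e7))
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_setequal(variantIds(ldClump(tab, LDMatrix(r2))), c("A", "B"))
})

test_that("a missing LD matrix clumps on distance alone with a warning", {
  tab <- makeTable(c("A", "B"), beta = rep(0.1, 2), se = rep(0.01, 2),
                   pval = c(1e-10, 1e-9))
  expect_warning(out <- ldClump(tab), "no LD matrix")
  expect_equal(length(out), 2L)
})

test_that("strict mode flags variants absent from the LD matrix", {
  tab <- makeTable(c("A", "B"), beta = rep(0.1, 2), se = rep(0.01, 2),
                   pval = c(1e-10, 1e-9), position = c(1e6, 2e6))
  r2 <- matrix(1, 1, 1, dimnames = list("A", "A"))
  expect_error(ldClump(tab, LDMatrix(r2), strict = TRUE),
               class = "mr_unknown_variant_ld")
  expect_equal(length(suppressWarnings(ldClump(tab, LDMatrix(r2)))), 2L)
})

test_that("clump output is deterministic and pairwise independent", {
  set.seed(5)
  for (trial in 1:10) {
    k <- 12
    ids <- sprintf("s%02d", 1:k)
    tab <- makeTable(ids, beta = rep(0.1, k), se = rep(0.01, k),
                     pval = runif(k, 1e-12, 1e-8),
                     position = sort(sample.int(3e7, k)))
    m <- diag(k)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      m[i, j] <- m[j, i] <- sample(c(0, 0.2), 1)
    dimnames(m) <- list(ids, ids)
    ld <- LDMatrix(m)
    out <- ldClump(tab, ld)
    kept <- variantIds(out)
    # the globally best p-value always survives
    expect_true(ids[which.min(variants(tab)$pval)] %in% kept)
    # no retained pair is both near and correlated
    v <- variants(out)
    for (i in seq_along(kept)) for (j in seq_along(kept)) {
      if (i >= j) next
      near <- abs(v$position[i] - v$position[j]) <= 1e7
      expect_false(near && m[kept[i], kept[j]] >= 0.001)
    }
    # input order does not matter
    perm <- sample(k)
    tab2 <- AssociationTable(variants(tab)[perm, ])
    expect_equal(variantIds(ldClump(tab2, ld)), kept)
  }
})

test_that("F-statistics follow the variance-explained formula per SNP", {
  # printed-row check: EAF 0.401, beta -0.0576, N 34,217
  tab <- ischemicStrokeInstruments()
  f <- computeFStatistics(tab)
  expect_equal(f$r2[1], 2 * 0.401 * 0.599 * 0.0576^2, tolerance = 1e-12)
  expect_equal(f$f_stat[1], f$r2[1] * (34217 - 2) / (1 - f$r2[1]),
               tolerance = 1e-12)
  expect_equal(f$f_stat[1], 54.62, tolerance = 1e-3)
  expect_gt(min(f$f_stat), 10)

  zero <- makeTable("rs1", beta = 0, se = 0.01)
  fz <- computeFStatistics(zero)
  expect_equal(fz$r2, 0)
  expect_equal(fz$f_stat, 0)

  noeaf <- makeTable("rs1", beta = 0.1, se = 0.01, eaf = NA)
  expect_error(computeFStatistics(noeaf), class = "mr_missing_field")
})

test_that("F increases with |beta| and with N", {
  f <- function(eaf, beta, n)
    computeFStatistics(makeTable("x", beta = beta, se = 0.01, eaf = eaf,
                                 n = n))$f_stat
  set.seed(9)
  for (trial in 1:20) {
    eaf <- runif(1, 0.05, 0.95); beta <- runif(1, 0.01, 0.3)
    n <- sample(1000:50000, 1)
    expect_gt(f(eaf, beta * 1.5, n), f(eaf, beta, n))
    expect_gt(f(eaf, beta, n * 2L), f(eaf, beta, n))
  }
})

test_that("Steiger filter keeps exposure-to-outcome instruments only", {
  h <- makeH(bx = c(0.2, 0.01, 0.1), by = c(0.02, 0.3, 0.1),
             seOut = rep(0.01, 3))
  st <- steigerFilter(h)
  expect_equal(st$diagnostics$steiger_direction,
               c("exposure_to_outcome", "outcome_to_exposure", "ambiguous"))
  expect_equal(variantIds(st$instruments), "v01")
  expect_setequal(exclusions(st$instruments)$reason,
                  c("steiger-reverse", "steiger-ambiguous"))
  # swapping the sides reverses the direction
  h2 <- makeH(bx = c(0.02, 0.1, 0.1), by = c(0.2, 0.01, 0.05),
              seOut = rep(0.01, 3))
  st2 <- steigerFilter(h2)
  expect_equal(st2$diagnostics$steiger_direction[1], "outcome_to_exposure")

  noeaf <- makeH(bx = c(0.1, 0.2), by = c(0.01, 0.02), seOut = rep(0.01, 2))
  noeaf@instruments$eaf_out <- NA_real_
  expect_error(steigerFilter(noeaf), class = "mr_missing_field")
})

test_that("selection pipeline removes one engineered failure per stage", {
  ids <- sprintf("snp%d", 1:6)
  ex <- assocDf(ids, beta = rep(0.3, 6), se = rep(0.01, 6),
                pval = rep(1e-20, 6), eaf = rep(0.3, 6), n = 20000L)
  ex$pval[1] <- 1e-4          # fails genome-wide significance
  ex$position[3] <- ex$position[4] + 5e4  # clumped into snp4 (lower p below)
  ex$pval[3] <- 1e-19
  ex$beta[5] <- 0.012         # weak instrument: F < 10
  exposure <- AssociationTable(ex, traitType = "binary")

  ou <- assocDf(ids, beta = 0.03 * ex$beta, se = rep(0.005, 6),
                pval = rep(0.5, 6), eaf = rep(0.3, 6), n = 50000L)
  ou$beta[6] <- 0.5           # reverse causation: outcome r2 exceeds exposure
  outcome <- AssociationTable(ou)

  r2 <- diag(6); dimnames(r2) <- list(ids, ids)
  r2[3, 4] <- r2[4, 3] <- 0.8
  res <- selectInstruments(exposure, outcome, ld = LDMatrix(r2))

  expect_setequal(variantIds(res$instruments), c("snp2", "snp4"))
  aud <- res$audit
  expect_equal(aud$stage,
               c("pvalue", "maf", "clump", "harmonize", "fstat", "steiger"))
  removed <- aud[aud$n_removed > 0, ]
  expect_equal(nrow(removed), 4L)
  expect_equal(removed$removed[removed$stage == "pvalue"], "snp1")
  expect_equal(removed$removed[removed$stage == "clump"], "snp3")
  expect_equal(removed$removed[removed$stage == "fstat"], "snp5")
  expect_equal(removed$removed[removed$stage == "steiger"], "snp6")
  # counts telescope: input = output + total removals
  expect_equal(aud$n_in - aud$n_removed, aud$n_out)
  expect_equal(aud$n_in[1] - sum(aud$n_removed), aud$n_out[6])
})

test_that("an impossible threshold reports the stage that emptied the set", {
  tab <- ischemicStrokeInstruments()
  err <- expect_error(
    selectQuiet(tab, tab, config = SelectionConfig(pvalThreshold = 1e-300,
                                                   steiger = FALSE)),
    class = "mr_empty_selection")
  expect_equal(err$stage, "pvalue")
})
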