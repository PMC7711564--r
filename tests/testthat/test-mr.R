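test_that("Wald ratio and its delta-method SE follow the definitions", {
  r <- waldRatio(data.frame(beta_exposure = 0.1, se_exposure = 0.01,
                            beta_outcome = 0.2, se_outcome = 0.05))
  expect_equal(r$estimate, 2)
  expect_equal(r$se, 0.5)

  expect_equal(waldRatio(data.frame(beta_exposure = 0.1, se_exposure = 0.01,
                                    beta_outcome = 0, se_outcome = 0.05))$estimate,
               0)
  # se = se_out / |beta_exp|
  r2 <- waldRatio(data.frame(beta_exposure = 0.5, se_exposure = 0.01,
                             beta_outcome = 0.1, se_outcome = 0.05))
  expect_equal(r2$se, 0.1)
  expect_error(waldRatio(data.frame(beta_exposure = 0, se_exposure = 0.01,
                                    beta_outcome = 0.1, se_outcome = 0.05)),
               "zero")
})

test_that("IVW pools ratios with inverse-variance weights", {
  a1 <- data.frame(beta_exposure = 0.1, se_exposure = 0.01,
                   beta_outcome = 0.03, se_outcome = 0.02)
  expect_equal(mrIVW(a1)$estimate, waldRatio(a1)$estimate)
  expect_equal(mrIVW(a1)$se, waldRatio(a1)$se)

  # identical ratios with equal SEs: pooled = ratio, se shrinks by sqrt(k)
  k <- 4
  ak <- data.frame(beta_exposure = rep(0.1, k), se_exposure = 0.01,
                   beta_outcome = rep(0.05, k), se_outcome = 0.02)
  rk <- mrIVW(ak)
  expect_equal(rk$estimate, 0.5)
  expect_equal(rk$se, (0.02 / 0.1) / sqrt(k))
  expect_equal(rk$q, 0)

  # unbiased under no pleiotropy
  set.seed(51)
  est <- vapply(1:200, function(i) {
    mrIVW(simSummaryAssocs(50, 0.3, seed = 1000 + i))$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.02)
})

test_that("single-instrument 2SLS, Wald ratio and IVW coincide", {
  set.seed(52)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  x <- 0.3 * g + rnorm(n)
  y <- 0.5 * x + rnorm(n)
  d <- data.frame(score = g, exposure = x, outcome = y)
  tsls <- suppressWarnings(
    twoStageLeastSquares(d, d, "score", "exposure", "outcome"))
  gm <- cbind(v1 = g)
  assoc <- data.frame(
    beta_exposure = perVariantAssoc(gm, x)$beta,
    se_exposure = perVariantAssoc(gm, x)$se,
    beta_outcome = perVariantAssoc(gm, y)$beta,
    se_outcome = perVariantAssoc(gm, y)$se)
  expect_equal(tsls$estimate, waldRatio(assoc)$estimate, tolerance = 1e-8)
  expect_equal(tsls$estimate, mrIVW(assoc)$estimate, tolerance = 1e-8)
})

test_that("2SLS is immune to the confounding that biases OLS", {
  rep <- simTslsRep(20000, 1000, beta_true = 0.35, seed = 53)
  ols <- coef(lm(outcome ~ exposure, data = rep$d2))[2]
  expect_gt(ols - 0.35, 0.15)
  r <- twoStageLeastSquares(rep$d1, rep$d2, "score", "exposure", "outcome")
  expect_lt(abs(r$estimate - 0.35), 2.5 * r$se)
  expect_equal(r$n_stage1, 20000L)
  expect_equal(r$n_stage2, 1000L)
})

test_that("2SLS returns identity when outcome equals exposure and warns on weak instruments", {
  set.seed(54)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  x <- 0.4 * g + rnorm(n)
  d <- data.frame(score = g, exposure = x, outcome = x)
  expect_equal(suppressWarnings(
    twoStageLeastSquares(d, d, "score", "exposure", "outcome"))$estimate,
    1, tolerance = 1e-8)

  dw <- data.frame(score = rnorm(n), exposure = rnorm(n), outcome = rnorm(n))
  expect_warning(twoStageLeastSquares(dw, dw, "score", "exposure", "outcome"),
                 "weak instrument")
})

test_that("per-SD rescaling is exact and invertible", {
  r <- data.frame(estimate = 0.103, se = 0.02,
                  ci_low = 0.103 - 1.959964 * 0.02,
                  ci_high = 0.103 + 1.959964 * 0.02)
  s <- rescalePerExposureSD(r, 3.4)
  expect_equal(s$estimate, 0.3502)
  expect_equal(rescalePerExposureSD(r, 1), r)
  back <- rescalePerExposureSD(s, 1 / 3.4)
  expect_equal(back$estimate, r$estimate, tolerance = 1e-12)
  expect_equal(back$se, r$se, tolerance = 1e-12)
  expect_error(rescalePerExposureSD(r, 0), "positive")
})

test_that("MR-Egger separates directional pleiotropy from the slope", {
  expect_error(mrEgger(simSummaryAssocs(2, 0.3)), "at least 3")

  set.seed(55)
  fits0 <- lapply(1:150, function(i) mrEgger(simSummaryAssocs(50, 0.3,
                                                              seed = 2000 + i)))
  expect_lt(abs(mean(vapply(fits0, `[[`, 1, "egger_intercept"))), 0.005)
  expect_lt(abs(mean(vapply(fits0, `[[`, 1, "estimate")) - 0.3), 0.03)

  # constant directional pleiotropy loads on the intercept, not the slope
  fits1 <- lapply(1:150, function(i) {
    mrEgger(simSummaryAssocs(50, 0.3, pleiotropy = rep(0.05, 50),
                             seed = 3000 + i))
  })
  expect_equal(mean(vapply(fits1, `[[`, 1, "egger_intercept")), 0.05,
               tolerance = 0.01 / 0.05)
  expect_lt(abs(mean(vapply(fits1, `[[`, 1, "estimate")) - 0.3), 0.03)
})

test_that("weighted median follows the 50% weight-crossing definition", {
  # all ratios equal: estimate is that ratio exactly
  ae <- data.frame(beta_exposure = c(0.1, 0.2, 0.4), se_exposure = 0.01,
                   beta_outcome = c(0.05, 0.1, 0.2), se_outcome = 0.02)
  expect_equal(mrWeightedMedian(ae, n_boot = 50)$estimate, 0.5)

  # equal weights, ratios (1, 2, 9): plain median
  am <- data.frame(beta_exposure = rep(1, 3), se_exposure = 0.01,
                   beta_outcome = c(1, 2, 9), se_outcome = 0.5)
  expect_equal(mrWeightedMedian(am, n_boot = 50)$estimate, 2)

  expect_error(mrWeightedMedian(ae[1:2, ]), "at least 3")
})

test_that("weighted median resists 40% invalid instruments where IVW fails", {
  set.seed(56)
  wm <- numeric(100)
  ivw <- numeric(100)
  for (i in 1:100) {
    pl <- c(rep(0.05, 20), rep(0, 30))   # 40% invalid
    a <- simSummaryAssocs(50, 0.3, se_exp = 0.002, se_out = 0.002,
                          pleiotropy = pl, seed = 4000 + i)
    wm[i] <- mrWeightedMedian(a, n_boot = 10, seed = i)$estimate
    ivw[i] <- mrIVW(a)$estimate
  }
  expect_lt(abs(mean(wm) - 0.3), 0.05)
  expect_gt(mean(ivw) - 0.3, 0.1)
})

test_that("Steiger orientation follows the explained-variance comparison", {
  s <- steigerDirection(0.02, 10000, 0.002, 10000)
  expect_equal(s$orientation, "exposure->outcome")
  expect_lt(s$p, 0.001)

  expect_equal(steigerDirection(0.01, 500, 0.01, 500)$z, 0)
  expect_equal(steigerDirection(0.002, 1000, 0.02, 1000)$orientation,
               "outcome->exposure")
  expect_error(steigerDirection(1, 100, 0.5, 100), "0, 1")
})

test_that("Cochran Q flags discordant estimate pairs", {
  expect_equal(cochranQTwoEstimates(0.2, 0.05, 0.2, 0.08)$q, 0)
  expect_equal(cochranQTwoEstimates(0.2, 0.05, 0.2, 0.08)$p, 1)

  # directionally opposite genetic vs observational estimates, SEs from CIs
  se_obs <- seFromCI(0.05, 0.21)
  se_gen <- seFromCI(-0.35, -0.09)
  q <- cochranQTwoEstimates(0.13, se_obs, -0.22, se_gen)
  expect_gt(q$q, 3.84)
  expect_lt(q$p, 0.05)

  # doubling both SEs divides Q by 4 exactly
  q2 <- cochranQTwoEstimates(0.13, 2 * se_obs, -0.22, 2 * se_gen)
  expect_equal(q2$q, q$q / 4)
})

test_that("gene-proximity exclusion respects the strict distance boundary", {
  genes <- data.frame(chrom = "1", start = 5000000, end = 6000000)
  v <- data.frame(id = c("in", "far", "edge", "other_chr"),
                  chrom = c("1", "1", "1", "2"),
                  pos = c(5500000,            # inside the span
                          6000000 + 1000001,  # 1,000,001 bp past the edge
                          6000000 + 1000000,  # exactly 1,000,000 bp away
                          5500000))
  out <- excludeNearbyVariants(v, genes, window = 1e6)
  expect_setequal(out$id, c("far", "other_chr"))
  expect_setequal(attr(out, "exclusions")$id, c("in", "edge"))

  # empty gene list: identity
  expect_equal(nrow(excludeNearbyVariants(v, genes[0, ])), 4L)

  expect_error(excludeNearbyVariants(v, data.frame(chrom = "chr9",
                                                   start = 1, end = 10)),
               "chromosome")
})

test_that("summary-statistic harmonization flips swaps and drops ambiguity", {
  exp_stats <- data.frame(id = c("v1", "v2", "v3", "v4"),
                          effect_allele = c("A", "C", "G", "A"),
                          other_allele = c("G", "T", "A", "T"),
                          eaf = c(0.3, 0.2, 0.5, 0.1),
                          beta = c(0.1, 0.2, 0.15, 0.12), se = 0.01)
  out_stats <- data.frame(id = c("v1", "v2", "v3", "v4"),
                          effect_allele = c("G", "C", "C", "A"),
                          other_allele = c("A", "T", "A", "T"),
                          eaf = c(0.7, 0.2, 0.5, 0.1),
                          beta = c(0.05, 0.06, 0.07, 0.08), se = 0.02)
  h <- harmonizeSummaryStats(exp_stats, out_stats)
  # v1: allele swap -> outcome beta sign flips; v2: aligned;
  # v3: mismatch -> dropped; v4: palindromic at eaf 0.1 -> kept
  expect_setequal(h$id, c("v1", "v2", "v4"))
  expect_equal(h$beta_outcome[h$id == "v1"], -0.05)
  expect_equal(h$beta_outcome[h$id == "v2"], 0.06)

  # palindromic with ambiguous frequency is dropped
  exp_stats$eaf[4] <- 0.5
  h2 <- harmonizeSummaryStats(exp_stats, out_stats)
  expect_false("v4" %in% h2$id)
})
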