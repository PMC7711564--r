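test_that("genotype dosages follow Hardy-Weinberg proportions", {
  g <- simulateGenotypes(100000, 0.3, seed = 1)
  expect_true(all(g %in% 0:2))
  # binomial expectation: mean dosage 2 * maf
  expect_equal(mean(g), 0.6, tolerance = 0.01 / 0.6)

  # HWE chi-square non-significant at alpha = 0.001 for almost all variants
  g2 <- simulateGenotypes(5000, runif(200, 0.05, 0.45), seed = 2)
  pvals <- apply(g2, 2, function(col) {
    p <- mean(col) / 2
    expd <- 5000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(col + 1L, 3L)
    pchisq(sum((obs - expd)^2 / expd), df = 1, lower.tail = FALSE)
  })
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("genotype simulation is deterministic and validates inputs", {
  expect_identical(simulateGenotypes(50, c(0.1, 0.4), seed = 9),
                   simulateGenotypes(50, c(0.1, 0.4), seed = 9))
  expect_error(simulateGenotypes(0, 0.1, seed = 1), "positive")
  expect_error(simulateGenotypes(10, 0.6, seed = 1), "frequency")
  expect_error(simulateGenotypes(10, 0, seed = 1), "frequency")
  # vanishing maf: all-zero column with probability ~ 1
  expect_true(all(simulateGenotypes(4, 1e-9, seed = 3) == 0))
})

test_that("exposure variance explained is calibrated to target", {
  # perfect instrument: exposure is an affine function of the score
  g <- simulateGenotypes(500, rep(0.3, 5), seed = 4)
  x <- simulateExposure(g, rep(1, 5), target_r2 = 1, seed = 4)
  expect_equal(cor(as.numeric(x), attr(x, "score"), method = "spearman"), 1)

  # null weights: score is constant, r2 ~ 0
  x0 <- simulateExposure(g, rep(0, 5), target_r2 = 0.5, seed = 4)
  expect_lt(abs(cor(as.numeric(x0), rnorm(500))), 0.2)

  # calibration at large n: realized r2 within +-25% of target
  for (s in 1:3) {
    g <- simulateGenotypes(50000, rep(0.3, 20), seed = 100 + s)
    x <- simulateExposure(g, rep(1, 20), target_r2 = 0.02, seed = 200 + s)
    r2 <- summary(lm(as.numeric(x) ~ attr(x, "score")))$r.squared
    expect_gt(r2, 0.015)
    expect_lt(r2, 0.025)
  }

  expect_error(simulateExposure(g, rep(1, 20), target_r2 = 1.2, seed = 1),
               "target_r2")
})

test_that("exposure is rescaled to the stated natural-unit SD", {
  g <- simulateGenotypes(20000, rep(0.3, 10), seed = 6)
  x <- simulateExposure(g, rep(1, 10), 0.02, exposure_mean = 23.9,
                        exposure_sd = 3.4, seed = 6)
  expect_equal(sd(x), 3.4, tolerance = 0.03)
  expect_equal(mean(x), 23.9, tolerance = 0.1)
})

test_that("protein generator reproduces effects, unit variance and LOD flags", {
  n <- 10000
  set.seed(11)
  xz <- rnorm(n)
  u <- rnorm(n)
  mkTruth <- function(beta, gamma, k = 3) {
    new("TruthSet", exposureEffect = rep(beta, k),
        confounderLoading = rep(gamma, k),
        sharedFactorLoading = rep(0, k),
        pleiotropy = matrix(0, 2, k), proteinLogHR = rep(0, k),
        exposureLogHR = 0, confounderLogHR = 0,
        scoreWeights = rep(0, 2), mafs = rep(0.3, 2), confounder = u)
  }
  g <- matrix(0L, n, 2)

  # no effect, no confounding: protein uncorrelated with exposure
  p0 <- simulateProteins(xz, u, g, mkTruth(0, 0), rep(0, 3), seed = 12)
  expect_lt(max(abs(cor(xz, p0$npx))), 0.05)
  expect_equal(unname(apply(p0$npx, 2, sd)), rep(1, 3), tolerance = 0.05)

  # beta recovered by OLS within Monte-Carlo error
  p1 <- simulateProteins(xz, u, g, mkTruth(0.35, 0), rep(0, 3), seed = 13)
  fit <- lm(p1$npx[, 1] ~ xz)
  expect_equal(unname(coef(fit)[2]), 0.35,
               tolerance = 3 * summary(fit)$coefficients[2, 2] / 0.35)

  # confounding inflates the observational coefficient
  p2 <- simulateProteins(xz + 0.4 * u, u, g, mkTruth(0, 0.5), rep(0, 3),
                         seed = 14)
  expect_gt(coef(lm(p2$npx[, 1] ~ I(xz + 0.4 * u)))[2], 0.1)

  # extreme LOD quantile flags > 99%, determinism, input validation
  p3 <- simulateProteins(xz, u, g, mkTruth(0, 0), c(0.995, 0, 0), seed = 15)
  expect_gt(mean(p3$belowLOD[, 1]), 0.99)
  expect_equal(sum(p3$belowLOD[, 2]), 0)
  expect_identical(
    simulateProteins(xz, u, g, mkTruth(0, 0), rep(0.1, 3), seed = 16),
    simulateProteins(xz, u, g, mkTruth(0, 0), rep(0.1, 3), seed = 16))
  expect_error(simulateProteins(xz, u, g, mkTruth(0, 0), c(1, 0, 0), 1),
               "lod_quantile")
})

test_that("survival times follow the proportional-hazards model", {
  # null effect: two groups have similar event rates
  x <- cbind(group = rep(0:1, each = 5000))
  s0 <- simulateSurvival(x, 0, followup_years = 10, seed = 21)
  r <- tapply(s0$event, x[, 1], mean)
  expect_lt(abs(r[1] - r[2]), 0.03)

  # known log HR recovered by a Cox fit (single draw, so allow 3 SE)
  z <- cbind(z = rnorm(20000))
  s1 <- simulateSurvival(z, 0.2, followup_years = 10, seed = 22)
  fit <- fitCox(cbind(s1, z = z[, 1]), "z")
  expect_lt(abs(fit$log_hr - 0.2), 3 * fit$se)

  # full dropout: no events, times in (0, followup]
  s2 <- simulateSurvival(z[1:100, , drop = FALSE], 0.2, 10,
                         censor_rate = 1, seed = 23)
  expect_equal(sum(s2$event), 0)
  expect_true(all(s2$time > 0 & s2$time <= 10))

  expect_error(simulateSurvival(z, 0.2, followup_years = -1, seed = 1),
               "followup")
  expect_error(simulateSurvival(z, c(0.1, 0.2), 10, seed = 1), "length")
})

test_that("makeStudy assembles a consistent nested design deterministically", {
  study <- fixtureStudy()
  cfg <- simConfig(study)
  expect_equal(nrow(genotypeDosage(study)), cfg@nGwas)
  expect_equal(ncol(genotypeDosage(study)), cfg@nVariants)
  expect_equal(ncol(subcohortSE(study)), cfg@nSubcohort)
  expect_equal(nrow(subcohortSE(study)), length(cfg@proteinEffects))
  expect_true(all(colnames(subcohortSE(study)) %in%
                    covariateTable(study)$id))

  # identical config => byte-identical serialized outputs
  cfg2 <- simConfigDefault(nGwas = 800L, nSubcohort = 150L,
                           nVariants = 15L, seed = 7L)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  writeStudy(makeStudy(cfg2), d1)
  writeStudy(makeStudy(cfg2), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("VCF export writes one record per variant with valid genotypes", {
  study <- makeStudy(simConfigDefault(nGwas = 50L, nSubcohort = 20L,
                                      nVariants = 8L, seed = 2L))
  path <- file.path(tempdir(), "geno.vcf")
  exportVCF(study, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 8L)
  gt <- unlist(strsplit(body[1], "\t"))[-(1:9)]
  expect_length(gt, 50L)
  expect_true(all(gt %in% c("0/0", "0/1", "1/1")))
})
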