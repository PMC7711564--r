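test_that("standardization is idempotent and supports a reference SD", {
  z <- standardize(c(1, 2, 3))
  expect_equal(sd(z), 1)
  expect_equal(mean(z), 0)
  expect_equal(standardize(z), z)

  # external reference SD: per-unit effects rescale by that SD
  x <- rnorm(50, 24, 2)
  zr <- standardize(x, reference_sd = 3.4)
  expect_equal(zr, (x - mean(x)) / 3.4)

  expect_error(standardize(rep(2, 10)), "zero-variance")
  expect_error(standardize(x, reference_sd = 0), "positive")
})

test_that("per-SD betas equal per-unit betas times the exposure SD", {
  study <- fixtureStudy()
  se <- subcohortSE(study)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  prot <- standardize(SummarizedExperiment::assay(se, "npx")[1, ])
  dat <- cbind(.p = prot, cd)
  dat$exposure_ref <- standardize(dat$exposure, reference_sd = 3.4)
  per_sd <- adjustedLinearAssoc(dat, ".p", "exposure_ref",
                                adjustmentSet(c("age", "sex")))
  per_unit <- adjustedLinearAssoc(dat, ".p", "exposure",
                                  adjustmentSet(c("age", "sex")))
  expect_equal(per_sd$beta, per_unit$beta * 3.4, tolerance = 1e-10)
})

test_that("low-detectability proteins are excluded by the >99% rule", {
  set.seed(41)
  panel <- matrix(rnorm(300), 100, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  flags <- matrix(FALSE, 100, 3, dimnames = dimnames(panel))
  flags[, 2] <- TRUE               # 100% below LOD
  flags[1:99, 3] <- TRUE           # 99% exactly: retained at default 0.99
  out <- excludeLowDetect(panel, flags)
  expect_equal(colnames(out), c("a", "c"))
  expect_equal(attr(out, "excluded"), "b")
  # max_below_frac = 1 keeps everything
  expect_equal(ncol(excludeLowDetect(panel, flags, max_below_frac = 1)), 3L)

  # a 92-protein panel with 2 proteins > 99% below LOD leaves 90
  study <- fixtureStudy()
  se <- subcohortSE(study)
  kept <- excludeLowDetect(t(SummarizedExperiment::assay(se, "npx")),
                           t(SummarizedExperiment::assay(se, "belowLOD")))
  expect_equal(ncol(kept), 90L)
  expect_length(attr(kept, "excluded"), 2L)
})

test_that("adjusted association is invariant to orthogonal covariates", {
  set.seed(42)
  n <- 200
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  ortho <- resid(lm(rnorm(n) ~ x))   # exactly orthogonal to x
  d <- data.frame(y = y, x = x, ortho = ortho)
  b0 <- adjustedLinearAssoc(d, "y", "x")$beta
  b1 <- adjustedLinearAssoc(d, "y", "x", adjustmentSet("ortho"))$beta
  expect_equal(b0, b1, tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the offending column", {
  set.seed(43)
  d <- data.frame(y = rnorm(50), x = rnorm(50))
  d$x2 <- 2 * d$x
  expect_error(adjustedLinearAssoc(d, "y", "x", adjustmentSet("x2")),
               "collinear.*x2")
})

test_that("null exposure association has nominal type-I error", {
  set.seed(44)
  hits <- replicate(400, {
    n <- 80
    adjustedLinearAssoc(data.frame(y = rnorm(n), x = rnorm(n)),
                        "y", "x")$p < 0.05
  })
  expect_gt(mean(hits), 0.025)
  expect_lt(mean(hits), 0.08)
})

test_that("a known effect is recovered with near-nominal CI coverage", {
  set.seed(45)
  cover <- replicate(100, {
    n <- 628
    x <- rnorm(n)
    y <- 0.35 * x + sqrt(1 - 0.35^2) * rnorm(n)
    r <- adjustedLinearAssoc(data.frame(y = y, x = x), "y", "x")
    abs(r$beta - 0.35) <= 2 * r$se
  })
  expect_gte(mean(cover), 0.90)
})

test_that("Benjamini-Hochberg step-up matches the hand computation", {
  r <- bhFdr(c(0.01, 0.02, 0.04, 0.05), q = 0.05)
  expect_equal(r$p_adjusted, c(0.04, 0.04, 0.05, 0.05))
  expect_true(all(r$significant_fdr))
  expect_true(all(r$p_adjusted >= r$p))

  expect_false(any(bhFdr(rep(1, 10))$significant_fdr))
  expect_true(bhFdr(0.01, q = 0.05)$significant_fdr)
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("panel-wide associations flag the simulated causal proteins", {
  study <- fixtureStudy()
  se <- subcohortSE(study)
  panel <- apply(t(SummarizedExperiment::assay(se, "npx")), 2, standardize)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  res <- panelExposureAssoc(panel, cd, "exposure_z",
                            adjustmentSet(c("age", "sex", "region")))
  truth <- truthSet(study)
  causal <- truth@exposureEffect != 0
  # strong causal proteins dominate the FDR-significant set
  expect_gt(mean(res$significant_fdr[causal][truth@exposureEffect[causal] >=
                                               0.35]), 0.8)
  # null proteins are only confounder-biased; most stay non-significant
  expect_lt(mean(res$significant_fdr[!causal]), 0.4)
  expect_true(all(res$p_adjusted >= res$p))
})

test_that("ordered p-value band counts agree with their construction", {
  # overwhelming signal: every p-value surpasses
  rb <- renyiBand(rep(1e-10, 90))
  expect_equal(rb$n_surpass, 90L)

  # BH band: surpassing count equals the BH-significant count
  set.seed(46)
  p <- c(runif(80), rep(1e-4, 10))
  expect_equal(renyiBand(p, q = 0.05)$n_surpass,
               sum(bhFdr(p, q = 0.05)$significant_fdr))

  # pointwise band under the null rejects about 5%
  set.seed(47)
  counts <- replicate(200, renyiBand(runif(90), band = "pointwise")$n_surpass)
  expect_equal(mean(counts) / 90, 0.05, tolerance = 0.3)

  expect_error(renyiBand(0.5), "at least two")
})
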