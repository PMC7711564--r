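#' Split-sample two-stage least squares
#'
#' Stage 1 regresses the exposure on the allele score (plus covariates) in
#' the large genotyped sample; stage 2 regresses the outcome on the exposure
#' predicted from the stage-1 coefficients (plus covariates) in the outcome
#' sample, which may be a subset of stage 1.  The reported SE is the
#' model-based stage-2 SE: first-stage sampling error is ignored, which is
#' defensible when the stage-1 sample dwarfs stage 2; `n_boot > 0` adds a
#' nonparametric bootstrap over both stages as a check.
#'
#' @param data1 stage-1 data.frame (score, exposure, covariates).
#' @param data2 stage-2 data.frame (score, outcome, covariates).
#' @param score,exposure,outcome column names.
#' @param covariates1,covariates2 covariate name vectors per stage (the
#'   stage-2 set defaults to the stage-1 set).
#' @param n_boot bootstrap replicates for the optional two-stage SE.
#' @param seed seed for the bootstrap.
#' @return one-row `MRResult` data.frame (method `"tsls"`) with columns
#'   estimate, se, ci, p, and `n_stage1`/`n_stage2`; bootstrap SE as
#'   `se_boot` when requested.  Warns (but still returns) when the
#'   instrument is weak (partial F < 10).
#' @export
twoStageLeastSquares <- function(data1, data2, score, exposure, outcome,
                                 covariates1 = character(),
                                 covariates2 = covariates1,
                                 n_boot = 0, seed = 1L) {
  data1 <- as.data.frame(data1)
  data2 <- as.data.frame(data2)
  stopifnot(score %in% names(data1), score %in% names(data2),
            exposure %in% names(data1), outcome %in% names(data2))
  fitStages <- function(d1, d2) {
    rhs1 <- paste(c(sprintf("`%s`", score),
                    if (length(covariates1)) sprintf("`%s`", covariates1)),
                  collapse = " + ")
    f1 <- lm(as.formula(paste(sprintf("`%s`", exposure), "~", rhs1)),
             data = d1)
    mm2 <- model.matrix(as.formula(paste("~", rhs1)), d2)
    d2$.xhat <- drop(mm2[, names(coef(f1)), drop = FALSE] %*% coef(f1))
    rhs2 <- paste(c(".xhat",
                    if (length(covariates2)) sprintf("`%s`", covariates2)),
                  collapse = " + ")
    f2 <- lm(as.formula(paste(sprintf("`%s`", outcome), "~", rhs2)),
             data = d2)
    list(f1 = f1, f2 = f2)
  }
  fits <- fitStages(data1, data2)
  covdf <- if (length(covariates1))
    data1[, covariates1, drop = FALSE] else NULL
  strength <- instrumentStrength(data1[[score]], data1[[exposure]], covdf)
  if (strength$f_statistic < 10)
    warning(sprintf("weak instrument: partial F = %.2f < 10",
                    strength$f_statistic))
  sm <- summary(fits$f2)$coefficients
  est <- sm[".xhat", 1]
  se <- sm[".xhat", 2]
  out <- mrResultRow("tsls", est, se, n_variants = NA_integer_,
                     n_stage1 = nrow(data1), n_stage2 = nrow(data2))
  out$f_stage1 <- strength$f_statistic
  if (n_boot > 0) {
    set.seed(seed)
    bb <- vapply(seq_len(n_boot), function(b) {
      i1 <- sample.int(nrow(data1), replace = TRUE)
      i2 <- sample.int(nrow(data2), replace = TRUE)
      f <- fitStages(data1[i1, , drop = FALSE], data2[i2, , drop = FALSE])
      coef(f$f2)[".xhat"]
    }, numeric(1))
    out$se_boot <- sd(bb)
  }
  out
}

#' Rescale an estimate from per-unit to per-SD exposure
#'
#' Multiplies the estimate, SE and CI of a result row by the exposure SD, so
#' an effect per natural exposure unit becomes an effect per 1-SD exposure
#' (e.g. per 3.4 adiposity units).
#'
#' @param result a result data.frame with columns estimate (or beta), se,
#'   ci_low, ci_high.
#' @param exposure_sd positive SD on the natural unit scale.
#' @return the rescaled result.
#' @examples
#' r <- data.frame(estimate = 0.103, se = 0.02,
#'                 ci_low = 0.103 - 1.959964 * 0.02,
#'                 ci_high = 0.103 + 1.959964 * 0.02)
#' rescalePerExposureSD(r, 3.4)$estimate
#' @export
rescalePerExposureSD <- function(result, exposure_sd) {
  if (exposure_sd <= 0) stop("exposure_sd must be positive")
  cols <- intersect(c("estimate", "beta", "se", "ci_low", "ci_high",
                      "se_boot"), names(result))
  result[cols] <- result[cols] * exposure_sd
  result
}
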