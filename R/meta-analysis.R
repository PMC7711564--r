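#' Standard error from a reported confidence interval
#'
#' Inverts CI construction: on the linear scale
#' `(high - low) / (2 z)`; on the log scale (for ratio measures such as HR,
#' RR, OR) `(log(high) - log(low)) / (2 z)`, with `z` the standard-normal
#' quantile at `(1 + level) / 2`.
#'
#' @param low,high interval bounds (`high > low`; both positive on the log
#'   scale).
#' @param level coverage level in (0, 1).
#' @param scale `"linear"` or `"log"`.
#' @return the standard error (of the log estimate when `scale = "log"`).
#' @examples
#' seFromCI(0.13, 0.29)               # linear CI
#' seFromCI(1.16, 1.36, scale = "log") # SE of the log hazard ratio
#' @export
seFromCI <- function(low, high, level = 0.95, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (any(high <= low)) stop("high must exceed low")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  z <- qnorm((1 + level) / 2)
  if (scale == "log") {
    if (any(low <= 0)) stop("log-scale bounds must be positive")
    (log(high) - log(low)) / (2 * z)
  } else {
    (high - low) / (2 * z)
  }
}

## normalize a study-estimate table to (study, beta, se) on a common
## additive scale; log-scale rows enter as ratio estimates with ratio CIs
normalizeEstimates <- function(estimates) {
  est <- as.data.frame(estimates)
  if (!"scale" %in% names(est)) est$scale <- "linear"
  if (!"level" %in% names(est)) est$level <- 0.95
  if (length(unique(est$scale)) > 1)
    stop("mixed scales: convert estimates to a common scale first")
  has_se <- "se" %in% names(est) & if ("se" %in% names(est))
    !is.na(est$se) else FALSE
  beta <- ifelse(est$scale == "log", log(est$estimate), est$estimate)
  se <- numeric(nrow(est))
  for (i in seq_len(nrow(est))) {
    if (isTRUE(has_se[i])) {
      if (any(c("ci_low", "ci_high") %in% names(est)) &&
          !all(is.na(c(est$ci_low[i], est$ci_high[i]))))
        stop("provide exactly one of se or ci per estimate")
      se[i] <- est$se[i]
    } else {
      se[i] <- seFromCI(est$ci_low[i], est$ci_high[i], est$level[i],
                        scale = est$scale[i])
    }
  }
  data.frame(study = est$study, beta = beta, se = se,
             scale = est$scale, stringsAsFactors = FALSE)
}

metaResultRow <- function(fit, model, k) {
  est <- as.numeric(fit$beta)
  se <- fit$se
  data.frame(pooled = est, se = se,
             ci_low = est - Z95 * se, ci_high = est + Z95 * se,
             p = waldP(est, se), model = model, k = k,
             q = fit$QE, df = k - 1L,
             q_p = if (k > 1L) fit$QEp else NA_real_,
             i2 = fit$I2 %||% 0, tau2 = fit$tau2 %||% 0,
             stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools study estimates with weights `1/se^2`
#' (`pooled = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`), reporting Cochran
#' Q and I-squared.  Ratio-scale estimates (HR/RR/OR) are pooled on the log
#' scale.
#'
#' @param estimates study-estimate table: columns `study`, `estimate`,
#'   `scale` (`"linear"` or `"log"`), and either `se` or
#'   `ci_low`/`ci_high` (+ optional `level`).
#' @return one-row `MetaResult` data.frame.
#' @examples
#' metaFixed(data.frame(study = c("a", "b"), estimate = c(0.1, 0.3),
#'                      se = c(0.05, 0.05), scale = "linear"))
#' @export
metaFixed <- function(estimates) {
  est <- normalizeEstimates(estimates)
  if (nrow(est) < 1) stop("need at least one estimate")
  fit <- metafor::rma.uni(yi = est$beta, sei = est$se, method = "FE")
  out <- metaResultRow(fit, "fixed", nrow(est))
  out$tau2 <- 0
  out
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance with weights `1/(se^2 + tau2)`;
#' reduces to the fixed-effect result when Q <= df (tau2 truncates at 0).
#'
#' @inheritParams metaFixed
#' @return one-row `MetaResult` data.frame.
#' @export
metaRandom <- function(estimates) {
  est <- normalizeEstimates(estimates)
  if (nrow(est) < 2) stop("need at least two estimates")
  fit <- metafor::rma.uni(yi = est$beta, sei = est$se, method = "DL")
  metaResultRow(fit, "random", nrow(est))
}
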