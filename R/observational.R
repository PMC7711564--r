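#' Standardize a numeric vector
#'
#' Centers at the mean and scales to unit SD, or — when a `reference_sd`
#' from a larger reference population is supplied — scales by that SD
#' instead so effects can be expressed per reference-population SD (e.g. per
#' 3.4 adiposity units).
#'
#' @param values numeric vector (NAs tolerated).
#' @param reference_sd optional externally supplied SD.
#' @return z-scored vector.
#' @examples
#' sd(standardize(c(1, 2, 3)))
#' @export
standardize <- function(values, reference_sd = NULL) {
  mu <- mean(values, na.rm = TRUE)
  if (is.null(reference_sd)) {
    s <- sd(values, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("zero-variance vector cannot be standardized without reference_sd")
  } else {
    if (reference_sd <= 0) stop("reference_sd must be positive")
    s <- reference_sd
  }
  (values - mu) / s
}

#' Exclude proteins with excessive below-detection fractions
#'
#' Drops panel columns whose below-LOD fraction exceeds `max_below_frac`
#' (default 0.99, i.e. proteins undetectable in more than 99% of samples).
#'
#' @param panel numeric matrix, individuals x proteins.
#' @param lod_flags logical matrix of the same shape.
#' @param max_below_frac maximum tolerated below-LOD fraction.
#' @return the retained panel, with attributes `"excluded"` (names) and
#'   `"below_frac"` (per-protein fractions).
#' @export
excludeLowDetect <- function(panel, lod_flags, max_below_frac = 0.99) {
  stopifnot(all(dim(panel) == dim(lod_flags)))
  frac <- colMeans(lod_flags)
  keep <- frac <= max_below_frac
  out <- panel[, keep, drop = FALSE]
  attr(out, "excluded") <- colnames(panel)[!keep]
  attr(out, "below_frac") <- frac
  out
}

#' Define a named covariate adjustment set
#'
#' @param covariates character vector of covariate names (columns of the
#'   analysis data; categorical covariates as factors with the desired
#'   reference level set).
#' @param label short identifier carried into result tables.
#' @return an `AdjustmentSet` (list with class attribute).
#' @export
adjustmentSet <- function(covariates, label = "adjusted") {
  structure(list(covariates = as.character(covariates), label = label),
            class = "AdjustmentSet")
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of a (z-scored) outcome on a (z-scored) exposure
#' plus the adjustment covariates, on complete cases.  The result is the
#' exposure coefficient with model-based SE and 95% CI.
#'
#' @param data data.frame holding outcome, exposure and covariates.
#' @param outcome,exposure column names.
#' @param adjustment an [adjustmentSet()] (or NULL for unadjusted).
#' @param trait label for the result row (defaults to `outcome`).
#' @return one-row data.frame (`AssocResult`): trait, beta, se, ci_low,
#'   ci_high, p, n, adjustment_set; attribute `"n_dropped"` counts
#'   incomplete rows removed.
#' @export
adjustedLinearAssoc <- function(data, outcome, exposure, adjustment = NULL,
                                trait = outcome) {
  covs <- if (is.null(adjustment)) character() else adjustment$covariates
  label <- if (is.null(adjustment)) "unadjusted" else adjustment$label
  cols <- c(outcome, exposure, covs)
  stopifnot(all(cols %in% names(data)))
  dat <- as.data.frame(data)[, cols, drop = FALSE]
  cc <- complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < length(covs) + 10)
    stop("too few complete cases for the covariate set")
  rhs <- paste(c(sprintf("`%s`", exposure),
                 if (length(covs)) sprintf("`%s`", covs)), collapse = " + ")
  form <- as.formula(paste(sprintf("`%s`", outcome), "~", rhs))
  mm <- model.matrix(form, dat)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- lm(form, data = dat)
  sm <- summary(fit)$coefficients
  row <- which(rownames(sm) == sprintf("`%s`", exposure) |
                 rownames(sm) == exposure)[1]
  beta <- sm[row, 1]
  se <- sm[row, 2]
  out <- data.frame(trait = trait, beta = beta, se = se,
                    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                    p = sm[row, 4], n = nrow(dat), adjustment_set = label,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up adjusted p-values with significance flags at rate `q`.
#'
#' @param pvalues numeric p-values in [0, 1].
#' @param q target FDR.
#' @return data.frame: p, p_adjusted, significant_fdr.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.04, 0.05), q = 0.05)
#' @export
bhFdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj, significant_fdr = adj <= q)
}

#' Panel-wide adjusted associations of an exposure with every protein
#'
#' Runs [adjustedLinearAssoc()] per protein column and applies
#' Benjamini-Hochberg control across the panel.  Per-protein model failures
#' are logged and skipped rather than aborting the panel.
#'
#' @param panel numeric matrix, individuals x proteins (z-scored columns).
#' @param data data.frame of exposure + covariates (same row order).
#' @param exposure exposure column name in `data`.
#' @param adjustment an [adjustmentSet()].
#' @param fdr_q FDR level for the significance flags.
#' @return data.frame of `AssocResult` rows plus `p_adjusted` and
#'   `significant_fdr`; attribute `"failures"` names skipped proteins.
#' @export
panelExposureAssoc <- function(panel, data, exposure, adjustment = NULL,
                               fdr_q = 0.05) {
  res <- vector("list", ncol(panel))
  fails <- character()
  for (j in seq_len(ncol(panel))) {
    trait <- colnames(panel)[j]
    dat <- cbind(.prot = panel[, j], as.data.frame(data))
    res[[j]] <- tryCatch(
      adjustedLinearAssoc(dat, ".prot", exposure, adjustment, trait = trait),
      error = function(e) {
        fails <<- c(fails, sprintf("%s: %s", trait, conditionMessage(e)))
        NULL
      })
  }
  out <- do.call(rbind, res)
  fdr <- bhFdr(out$p, q = fdr_q)
  out$p_adjusted <- fdr$p_adjusted
  out$significant_fdr <- fdr$significant_fdr
  attr(out, "failures") <- fails
  out
}

#' Ordered p-value (Renyi-style) band summary
#'
#' Orders the p-values against expected uniform order statistics on the
#' \eqn{-\log_{10}} scale and counts how many surpass a rejection band.  The
#' default band is the Benjamini-Hochberg step-up line at rate `q`, so the
#' surpassing set equals the BH-significant set; the `"pointwise"` band
#' counts p-values below a fixed `alpha` instead.  This is an approximate
#' stand-in for more specialized ordered-statistic constructions.
#'
#' @param pvalues at least two p-values.
#' @param band `"bh"` (default) or `"pointwise"`.
#' @param q BH rate for the default band.
#' @param alpha pointwise threshold.
#' @return list with `data` (rank, p, observed/expected/band on the
#'   \eqn{-\log_{10}} scale) and `n_surpass`.
#' @export
renyiBand <- function(pvalues, band = c("bh", "pointwise"), q = 0.05,
                      alpha = 0.05) {
  band <- match.arg(band)
  m <- length(pvalues)
  if (m < 2) stop("need at least two p-values")
  ord <- sort(pvalues)
  i <- seq_len(m)
  band_p <- if (band == "bh") q * i / m else rep(alpha, m)
  n_surpass <- if (band == "bh") {
    k <- which(ord <= band_p)
    if (length(k)) max(k) else 0L
  } else {
    sum(ord <= alpha)
  }
  list(data = data.frame(rank = i, p = ord,
                         neglog_p = -log10(ord),
                         expected_neglog = -log10(i / (m + 1)),
                         band_neglog = -log10(band_p)),
       n_surpass = as.integer(n_surpass),
       band = band)
}
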