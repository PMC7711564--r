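## Summary-statistic Mendelian randomization estimators.  All take a
## harmonized per-variant association table with columns beta_exposure,
## se_exposure, beta_outcome, se_outcome (one row per variant).

checkAssocs <- function(assocs, min_variants = 1L) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(need %in% names(assocs)))
    stop("association table must have columns: ", paste(need, collapse = ", "))
  if (nrow(assocs) < min_variants)
    stop(sprintf("need at least %d harmonized variants", min_variants))
  if (any(assocs$se_exposure <= 0) || any(assocs$se_outcome <= 0))
    stop("standard errors must be positive")
  invisible(assocs)
}

#' Wald ratio estimate from one variant
#'
#' Ratio of the variant-outcome to variant-exposure association, with the
#' first-order delta-method SE `se_outcome / |beta_exposure|`.
#'
#' @param assoc one-row association table (or a list with the four fields).
#' @return one-row `MRResult` data.frame (method `"wald"`).
#' @examples
#' waldRatio(data.frame(beta_exposure = 0.1, se_exposure = 0.01,
#'                      beta_outcome = 0.2, se_outcome = 0.05))
#' @export
waldRatio <- function(assoc) {
  assoc <- as.data.frame(assoc)[1, ]
  checkAssocs(assoc)
  if (assoc$beta_exposure == 0)
    stop("beta_exposure is zero: Wald ratio undefined")
  est <- assoc$beta_outcome / assoc$beta_exposure
  se <- assoc$se_outcome / abs(assoc$beta_exposure)
  mrResultRow("wald", est, se, n_variants = 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Fixed-effect inverse-variance-weighted mean of per-variant Wald ratios,
#' weighting by `1/se_ratio^2` with first-order ratio SEs.  With
#' `random = TRUE` the SE is inflated by the multiplicative overdispersion
#' factor `max(1, Q/df)` when the ratios are heterogeneous.
#'
#' @param assocs harmonized association table (>= 1 variant).
#' @param random apply multiplicative random-effects SE inflation.
#' @return one-row `MRResult` data.frame (method `"ivw"`) with
#'   heterogeneity columns `q`, `q_df`, `q_p`.
#' @export
mrIVW <- function(assocs, random = FALSE) {
  checkAssocs(assocs, 1L)
  if (any(assocs$beta_exposure == 0))
    stop("beta_exposure of zero: drop the variant first")
  r <- assocs$beta_outcome / assocs$beta_exposure
  se_r <- assocs$se_outcome / abs(assocs$beta_exposure)
  w <- 1 / se_r^2
  est <- sum(w * r) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- length(r)
  q <- sum(w * (r - est)^2)
  qdf <- max(k - 1L, 1L)
  if (random && k > 1L) se <- se * sqrt(max(1, q / qdf))
  out <- mrResultRow("ivw", est, se, n_variants = k)
  out$q <- q
  out$q_df <- k - 1L
  out$q_p <- if (k > 1L) pchisq(q, k - 1L, lower.tail = FALSE) else NA_real_
  out
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas (weights
#' `1/se_outcome^2`) with an intercept: the slope is the causal estimate and
#' the intercept measures average directional pleiotropy.  Exposure betas
#' are oriented positive before fitting, and SEs follow the multiplicative
#' random-effects convention (residual sigma floored at 1).
#'
#' @param assocs harmonized association table (>= 3 variants).
#' @return one-row `MRResult` data.frame (method `"egger"`) with
#'   `egger_intercept`, `intercept_se`, `intercept_p`.
#' @export
mrEgger <- function(assocs) {
  checkAssocs(assocs, 3L)
  sgn <- sign(assocs$beta_exposure)
  sgn[sgn == 0] <- 1
  bx <- abs(assocs$beta_exposure)
  by <- assocs$beta_outcome * sgn
  fit <- lm(by ~ bx, weights = 1 / assocs$se_outcome^2)
  sm <- summary(fit)
  infl <- 1 / min(sm$sigma, 1)
  slope <- sm$coefficients["bx", 1]
  slope_se <- sm$coefficients["bx", 2] * infl
  int <- sm$coefficients["(Intercept)", 1]
  int_se <- sm$coefficients["(Intercept)", 2] * infl
  out <- mrResultRow("egger", slope, slope_se, n_variants = nrow(assocs),
                     egger_intercept = int, intercept_se = int_se,
                     intercept_p = waldP(int, int_se))
  out
}

## weight-cumulative 50% crossing with linear interpolation
weightedMedianEstimate <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= cw[1]) return(r[1])
  if (0.5 >= cw[length(cw)]) return(r[length(r)])
  approx(cw, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' Median of the inverse-variance-weighted empirical distribution of Wald
#' ratios, consistent when valid variants hold more than half the weight.
#' The SE comes from a parametric bootstrap of the per-variant betas.
#'
#' @param assocs harmonized association table (>= 3 variants).
#' @param n_boot bootstrap replicates.
#' @param seed bootstrap seed.
#' @return one-row `MRResult` data.frame (method `"weighted_median"`).
#' @export
mrWeightedMedian <- function(assocs, n_boot = 1000L, seed = 1L) {
  checkAssocs(assocs, 3L)
  if (any(assocs$beta_exposure == 0))
    stop("beta_exposure of zero: drop the variant first")
  r <- assocs$beta_outcome / assocs$beta_exposure
  se_r <- assocs$se_outcome / abs(assocs$beta_exposure)
  w <- 1 / se_r^2
  est <- weightedMedianEstimate(r, w)
  set.seed(seed)
  k <- nrow(assocs)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(k, assocs$beta_exposure, assocs$se_exposure)
    by <- rnorm(k, assocs$beta_outcome, assocs$se_outcome)
    ok <- bx != 0
    rb <- by[ok] / bx[ok]
    wb <- (abs(bx[ok]) / assocs$se_outcome[ok])^2
    weightedMedianEstimate(rb, wb)
  }, numeric(1))
  se <- sd(boots)
  mrResultRow("weighted_median", est, se, n_variants = k)
}

#' Steiger directionality test
#'
#' Orients causality by comparing the variance the instrument explains in
#' the exposure versus the outcome: the association is oriented
#' exposure-to-outcome when `r2_exposure > r2_outcome`.  The test statistic
#' compares Fisher-transformed correlations across (possibly unequal)
#' sample sizes.
#'
#' @param r2_exposure,r2_outcome instrument variance explained, in [0, 1).
#' @param n_exposure,n_outcome the sample sizes behind each r-squared.
#' @return one-row data.frame: orientation, z, p, and the inputs.
#' @examples
#' steigerDirection(0.02, 10000, 0.002, 10000)
#' @export
steigerDirection <- function(r2_exposure, n_exposure, r2_outcome, n_outcome) {
  if (any(c(r2_exposure, r2_outcome) < 0) ||
      any(c(r2_exposure, r2_outcome) >= 1))
    stop("r-squared values must lie in [0, 1)")
  z_exp <- atanh(sqrt(r2_exposure))
  z_out <- atanh(sqrt(r2_outcome))
  z <- (z_exp - z_out) / sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  data.frame(orientation = ifelse(r2_exposure > r2_outcome,
                                  "exposure->outcome", "outcome->exposure"),
             z = z, p = 2 * pnorm(-abs(z)),
             r2_exposure = r2_exposure, r2_outcome = r2_outcome,
             stringsAsFactors = FALSE)
}

#' Cochran Q comparison of two estimates
#'
#' Tests heterogeneity between two estimates of the same quantity (e.g. a
#' genetic versus an observational association) with inverse-variance
#' weights; Q is referred to a 1-df chi-square.
#'
#' @param beta1,se1,beta2,se2 the two estimates and their SEs.
#' @return one-row data.frame (`HeterogeneityResult`): q, df, p.
#' @examples
#' cochranQTwoEstimates(0.13, 0.041, -0.22, 0.066)
#' @export
cochranQTwoEstimates <- function(beta1, se1, beta2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  w <- c(1 / se1^2, 1 / se2^2)
  b <- c(beta1, beta2)
  pooled <- sum(w * b) / sum(w)
  q <- sum(w * (b - pooled)^2)
  data.frame(q = q, df = 1L, p = pchisq(q, 1L, lower.tail = FALSE))
}

#' Exclude instrument variants near listed gene regions
#'
#' Drops variants whose distance to the nearest edge of any listed gene span
#' is at most `window` (default 1 Mbp), the usual guard against instruments
#' acting through the genes encoding the measured proteins.  Gene spans are
#' taken as 1-based closed coordinates (see [readGeneRegionsBed()] for BED
#' conversion).
#'
#' @param variants variant table with `id`, `chrom`, `pos`.
#' @param gene_regions data.frame with `chrom`, `start`, `end` (1-based
#'   closed).
#' @param window distance threshold in bp.
#' @return the retained variant table with an `"exclusions"` attribute.
#' @export
excludeNearbyVariants <- function(variants, gene_regions, window = 1e6) {
  if (nrow(gene_regions) == 0L) {
    attr(variants, "exclusions") <- data.frame(id = character(),
                                               reason = character())
    return(variants)
  }
  vchr <- as.character(variants$chrom)
  gchr <- as.character(gene_regions$chrom)
  if (length(intersect(unique(vchr), unique(gchr))) == 0L)
    stop("chromosome names of variants and gene regions do not overlap; ",
         "check naming style (e.g. '1' vs 'chr1')")
  vr <- GenomicRanges::GRanges(vchr,
                               IRanges::IRanges(variants$pos, variants$pos))
  gr <- GenomicRanges::GRanges(gchr,
                               IRanges::IRanges(gene_regions$start,
                                                gene_regions$end))
  hits <- GenomicRanges::distanceToNearest(vr, gr)
  drop <- rep(FALSE, nrow(variants))
  qh <- S4Vectors::queryHits(hits)
  ## GRanges gap = edge distance - 1 for non-overlap, 0 for overlap, so the
  ## strict edge-distance <= window rule maps to gap < window (or overlap)
  drop[qh] <- S4Vectors::mcols(hits)$distance < window
  out <- variants[!drop, , drop = FALSE]
  attr(out, "exclusions") <- data.frame(
    id = as.character(variants$id[drop]),
    reason = sprintf("within %g bp of a listed gene region", window),
    stringsAsFactors = FALSE)
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches two per-variant summary-statistic tables on variant id and
#' alleles; on an effect/other allele swap the outcome beta sign is flipped,
#' on any other allele mismatch the variant is dropped, and palindromic
#' (A/T, C/G) variants with effect-allele frequency in
#' (`palindromic_low`, `palindromic_high`) are dropped because strand cannot
#' be resolved.
#'
#' @param exposure_stats,outcome_stats data.frames with columns `id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`.
#' @param palindromic_low,palindromic_high ambiguous-frequency window.
#' @return harmonized association table (id, alleles, beta_exposure,
#'   se_exposure, beta_outcome, se_outcome) with a `"log"` attribute.
#' @export
harmonizeSummaryStats <- function(exposure_stats, outcome_stats,
                                  palindromic_low = 0.42,
                                  palindromic_high = 0.58) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  merged <- merge(exposure_stats, outcome_stats, by = "id",
                  suffixes = c("_exp", "_out"))
  log <- data.frame(id = character(), action = character(),
                    stringsAsFactors = FALSE)
  keep <- logical(nrow(merged))
  flip <- logical(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    r <- merged[i, ]
    pal <- !is.na(comp[r$effect_allele_exp]) &&
      comp[[r$effect_allele_exp]] == r$other_allele_exp
    if (pal && r$eaf_exp > palindromic_low && r$eaf_exp < palindromic_high) {
      log <- rbind(log, data.frame(id = r$id, action = "drop: palindromic"))
    } else if (r$effect_allele_exp == r$effect_allele_out &&
               r$other_allele_exp == r$other_allele_out) {
      keep[i] <- TRUE
    } else if (r$effect_allele_exp == r$other_allele_out &&
               r$other_allele_exp == r$effect_allele_out) {
      keep[i] <- TRUE
      flip[i] <- TRUE
      log <- rbind(log, data.frame(id = r$id, action = "flip: allele swap"))
    } else {
      log <- rbind(log, data.frame(id = r$id,
                                   action = "drop: allele mismatch"))
    }
  }
  out <- data.frame(id = merged$id[keep],
                    effect_allele = merged$effect_allele_exp[keep],
                    other_allele = merged$other_allele_exp[keep],
                    eaf = merged$eaf_exp[keep],
                    beta_exposure = merged$beta_exp[keep],
                    se_exposure = merged$se_exp[keep],
                    beta_outcome = ifelse(flip[keep], -1, 1) *
                      merged$beta_out[keep],
                    se_outcome = merged$se_out[keep],
                    stringsAsFactors = FALSE)
  attr(out, "log") <- log
  out
}
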