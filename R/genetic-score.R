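#' Filter variants by minor-allele frequency
#'
#' Retains variants whose minor-allele frequency `min(eaf, 1 - eaf)` is at
#' least `threshold`; the default 1% cutoff is the usual guard against
#' unstable weights for rare alleles.  Exclusions are recorded in the
#' `"exclusions"` attribute of the result (id, maf, reason).
#'
#' @param variants data.frame/DataFrame with at least `id` and `eaf`.
#' @param threshold MAF cutoff in (0, 0.5).
#' @return the retained variant table, with an `"exclusions"` attribute.
#' @examples
#' v <- data.frame(id = c("a", "b", "c"), eaf = c(0.005, 0.30, 0.988))
#' nrow(filterByMAF(v, 0.01))
#' @export
filterByMAF <- function(variants, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 0.5)
    stop("threshold must lie in (0, 0.5)")
  if (nrow(variants) == 0L) {
    warning("empty variant list")
    out <- variants
    attr(out, "exclusions") <- data.frame(id = character(), maf = numeric(),
                                          reason = character())
    return(out)
  }
  maf <- pmin(variants$eaf, 1 - variants$eaf)
  keep <- maf >= threshold
  out <- variants[keep, , drop = FALSE]
  attr(out, "exclusions") <- data.frame(
    id = as.character(variants$id[!keep]),
    maf = maf[!keep],
    reason = sprintf("maf %.4g below threshold %.4g", maf[!keep], threshold),
    stringsAsFactors = FALSE)
  out
}

#' Harmonize genotype dosages to a weight table's effect allele
#'
#' Genotype files coded to a different effect allele are flipped
#' (`2 - dosage`); variants whose allele pair does not match are dropped, as
#' are palindromic (A/T, C/G) variants with minor-allele frequency above
#' `palindromic_maf`, where strand cannot be resolved from frequency.
#'
#' @param genotypes dosage matrix, columns aligned to `genotype_alleles`.
#' @param genotype_alleles data.frame (id, effect_allele, other_allele)
#'   describing the genotype file's coding.
#' @param variants the weight table (id, effect_allele, other_allele, eaf).
#' @param palindromic_maf MAF above which palindromic variants are dropped.
#' @return list with `genotypes`, `variants` (both reduced/flipped) and a
#'   `log` data.frame of actions.
#' @export
harmonizeDosages <- function(genotypes, genotype_alleles, variants,
                             palindromic_maf = 0.42) {
  ids <- intersect(genotype_alleles$id, variants$id)
  log <- data.frame(id = character(), action = character(),
                    stringsAsFactors = FALSE)
  keep <- character()
  flip <- character()
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  for (id in ids) {
    ga <- genotype_alleles[genotype_alleles$id == id, ][1, ]
    va <- variants[variants$id == id, ][1, ]
    pal <- comp[[va$effect_allele]] == va$other_allele
    maf <- min(va$eaf, 1 - va$eaf)
    if (pal && maf > palindromic_maf) {
      log <- rbind(log, data.frame(id = id, action = "drop: palindromic"))
    } else if (ga$effect_allele == va$effect_allele &&
               ga$other_allele == va$other_allele) {
      keep <- c(keep, id)
    } else if (ga$effect_allele == va$other_allele &&
               ga$other_allele == va$effect_allele) {
      keep <- c(keep, id)
      flip <- c(flip, id)
      log <- rbind(log, data.frame(id = id, action = "flip: allele swap"))
    } else {
      log <- rbind(log, data.frame(id = id, action = "drop: allele mismatch"))
    }
  }
  gi <- match(keep, genotype_alleles$id)
  g <- genotypes[, gi, drop = FALSE]
  colnames(g) <- keep
  if (length(flip)) g[, flip] <- 2 - g[, flip, drop = FALSE]
  list(genotypes = g,
       variants = variants[match(keep, variants$id), , drop = FALSE],
       log = log)
}

#' Compute a weighted or unweighted allele score
#'
#' The weighted score sums effect-allele dosages weighted by the external
#' per-allele effects; the unweighted score sums dosages.  Missing dosages
#' are mean-imputed per variant (count recorded in the `"imputed"`
#' attribute).
#'
#' @param genotypes dosage matrix with columns aligned to `variants` (checked
#'   by name when both carry names).
#' @param variants variant table with `weight_beta` (ignored when
#'   `weighted = FALSE`).
#' @param weighted use the external weights.
#' @return numeric per-person score.
#' @examples
#' g <- cbind(v1 = c(1, 2, 0))
#' computeScore(g, data.frame(id = "v1", weight_beta = 0.1))
#' @export
computeScore <- function(genotypes, variants, weighted = TRUE) {
  if (ncol(genotypes) != nrow(variants))
    stop("genotype columns do not align to the variant table")
  if (!is.null(colnames(genotypes)) && !is.null(variants$id) &&
      !identical(as.character(colnames(genotypes)), as.character(variants$id)))
    stop("genotype columns do not align to the variant table")
  if (any(genotypes < 0 | genotypes > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  n_imputed <- 0L
  if (anyNA(genotypes)) {
    mu <- colMeans(genotypes, na.rm = TRUE)
    for (j in which(colSums(is.na(genotypes)) > 0)) {
      na <- is.na(genotypes[, j])
      n_imputed <- n_imputed + sum(na)
      genotypes[na, j] <- mu[j]
    }
  }
  w <- if (weighted) as.numeric(variants$weight_beta) else rep(1, nrow(variants))
  if (anyNA(w)) stop("missing weights; drop unweighted variants first")
  score <- drop(genotypes %*% w)
  attr(score, "imputed") <- n_imputed
  score
}

#' Quantify instrument strength
#'
#' Incremental variance in the exposure explained by the score after the
#' covariates, and the partial F statistic of the score term.  Without
#' covariates this reduces to the familiar identity
#' \eqn{F = r^2 (n - 2) / (1 - r^2)}.
#'
#' @param score per-person allele score.
#' @param exposure exposure vector.
#' @param covariates optional data.frame of adjustment covariates.
#' @return one-row data.frame: `f_statistic`, `r2`, `n`, `df1`, `df2`, `p`.
#' @examples
#' set.seed(1)
#' s <- rnorm(500); x <- 0.14 * s + rnorm(500)
#' instrumentStrength(s, x)
#' @export
instrumentStrength <- function(score, exposure, covariates = NULL) {
  if (sd(score) == 0) stop("constant score: F statistic undefined")
  n <- length(exposure)
  dat <- data.frame(.y = exposure, .s = score)
  rhs0 <- "1"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    dat <- cbind(dat, covariates)
    rhs0 <- paste(colnames(covariates), collapse = " + ")
  }
  p0 <- qr(model.matrix(as.formula(paste("~", rhs0)), dat))$rank
  if (n <= p0 + 2) stop("too few observations for the covariate set")
  f0 <- lm(as.formula(paste(".y ~", rhs0)), data = dat)
  f1 <- lm(as.formula(paste(".y ~", rhs0, "+ .s")), data = dat)
  rss0 <- sum(resid(f0)^2)
  rss1 <- sum(resid(f1)^2)
  tss <- sum((exposure - mean(exposure))^2)
  df2 <- n - p0 - 1L
  fstat <- (rss0 - rss1) / (rss1 / df2)
  data.frame(f_statistic = fstat,
             r2 = (rss0 - rss1) / tss,
             n = n, df1 = 1L, df2 = df2,
             p = pf(fstat, 1, df2, lower.tail = FALSE))
}
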