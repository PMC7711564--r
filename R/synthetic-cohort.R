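#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig]. Defaults describe the reference synthetic
#' study: 20,000 genotyped individuals (a desk-scale stand-in for a
#' biobank-scale population subset), a 628-person proteomics subcohort, 100
#' independent variants with minor-allele frequencies in (0.05, 0.45), an
#' allele score explaining 2.06% of exposure variance, exposure SD 3.4 on its
#' natural unit, a 92-protein panel in which 30 proteins carry nonzero
#' exposure effects, 10 carry nonzero log hazard ratios and 2 are almost
#' entirely below the detection limit, and 10 years of follow-up.
#'
#' @param nGwas,nSubcohort,nVariants sample sizes and variant count.
#' @param mafRange minor-allele-frequency range, pair in (0, 0.5].
#' @param varianceExplained target fraction of exposure variance explained by
#'   the allele score.
#' @param exposureMean,exposureSD exposure scale (natural units).
#' @param confounderExposure confounder loading on the standardized exposure.
#' @param proteinEffects per-protein causal effects (SD/SD); `NULL` uses the
#'   default 92-protein panel.
#' @param confounderProtein per-protein confounder loadings (recycled).
#' @param proteinSharedFactor per-protein shared-factor loadings (recycled).
#' @param pleiotropyMean,pleiotropySD distribution of per-variant direct
#'   protein effects; both 0 disables pleiotropy.
#' @param proteinLogHR per-protein log hazard ratios; `NULL` uses the default
#'   panel (10 nonzero).
#' @param hazardExposure,hazardConfounder,hazardAge,hazardSBP,hazardDiabetes
#'   log hazard ratios of the non-protein covariates.
#' @param baselineHazard baseline event rate per year.
#' @param weibullShape baseline-hazard Weibull shape (1 = exponential).
#' @param followupYears follow-up horizon in years.
#' @param censorRate probability of random dropout within follow-up.
#' @param lodQuantile per-protein below-detection fraction; `NULL` uses 0.02
#'   for all but the last two proteins, which get 0.995.
#' @param seed integer master seed.
#' @return a [SimConfig].
#' @examples
#' cfg <- simConfigDefault(nGwas = 2000L, seed = 7L)
#' cfg
#' @export
simConfigDefault <- function(nGwas = 20000L,
                             nSubcohort = 628L,
                             nVariants = 100L,
                             mafRange = c(0.05, 0.45),
                             varianceExplained = 0.0206,
                             exposureMean = 23.9,
                             exposureSD = 3.4,
                             confounderExposure = 0.3,
                             proteinEffects = NULL,
                             confounderProtein = 0.25,
                             proteinSharedFactor = 0,
                             pleiotropyMean = 0,
                             pleiotropySD = 0,
                             proteinLogHR = NULL,
                             hazardExposure = 0.08,
                             hazardConfounder = 0.2,
                             hazardAge = 0.6,
                             hazardSBP = 0.15,
                             hazardDiabetes = 0.3,
                             baselineHazard = 0.0274,
                             weibullShape = 1,
                             followupYears = 10,
                             censorRate = 0.1,
                             lodQuantile = NULL,
                             seed = 1L) {
  if (is.null(proteinEffects)) {
    # 30 of 90 analyzable proteins causal; the final two are the high-LOD pair
    proteinEffects <- c(rep(0.35, 10), rep(0.2, 10), rep(-0.2, 5),
                        rep(0.15, 5), rep(0, 62))
  }
  k <- length(proteinEffects)
  if (is.null(proteinLogHR)) {
    proteinLogHR <- rep(0, k)
    if (k >= 10) {
      proteinLogHR[1:10] <- c(0.19, 0.22, 0.17, 0.25, -0.26,
                              -0.27, 0.20, -0.19, 0.22, 0.34)
    }
  }
  if (is.null(lodQuantile)) {
    lodQuantile <- rep(0.02, k)
    if (k >= 2) lodQuantile[(k - 1):k] <- 0.995
  }
  new("SimConfig",
      nGwas = as.integer(nGwas),
      nSubcohort = as.integer(nSubcohort),
      nVariants = as.integer(nVariants),
      mafRange = as.numeric(mafRange),
      varianceExplained = varianceExplained,
      exposureMean = exposureMean,
      exposureSD = exposureSD,
      confounderExposure = confounderExposure,
      proteinEffects = proteinEffects,
      confounderProtein = rep_len(confounderProtein, k),
      proteinSharedFactor = rep_len(proteinSharedFactor, k),
      pleiotropyMean = pleiotropyMean,
      pleiotropySD = pleiotropySD,
      proteinLogHR = rep_len(proteinLogHR, k),
      hazardExposure = hazardExposure,
      hazardConfounder = hazardConfounder,
      hazardAge = hazardAge,
      hazardSBP = hazardSBP,
      hazardDiabetes = hazardDiabetes,
      baselineHazard = baselineHazard,
      weibullShape = weibullShape,
      followupYears = followupYears,
      censorRate = censorRate,
      lodQuantile = rep_len(lodQuantile, k),
      seed = as.integer(seed))
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws unlinked biallelic genotypes as `Binomial(2, maf)` effect-allele
#' counts, so genotype classes follow Hardy-Weinberg proportions
#' \eqn{p^2, 2pq, q^2} per variant.
#'
#' @param n number of individuals.
#' @param mafs vector of effect-allele frequencies, each in (0, 0.5].
#' @param seed integer seed.
#' @return integer matrix, `n` x `length(mafs)`, entries in \{0, 1, 2\}.
#' @examples
#' g <- simulateGenotypes(100, c(0.1, 0.3), seed = 1)
#' colMeans(g) / 2
#' @export
simulateGenotypes <- function(n, mafs, seed) {
  if (length(n) != 1L || n < 1) stop("n must be a positive count")
  if (any(mafs <= 0 | mafs > 0.5))
    stop("each minor-allele frequency must lie in (0, 0.5]")
  set.seed(seed)
  m <- length(mafs)
  g <- matrix(rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n, ncol = m)
  colnames(g) <- sprintf("v%04d", seq_len(m))
  g
}

#' Simulate an exposure driven by an allele score and a confounder
#'
#' The standardized exposure is
#' \eqn{z = \sqrt{r^2}\,S_z + c\,U + \sqrt{1 - r^2 - c^2}\,\epsilon},
#' where \eqn{S_z} is the standardized allele score, so the score explains
#' `target_r2` of exposure variance in expectation; the exposure is then
#' placed on its natural scale as `mean + sd * z`.
#'
#' @param genotypes dosage matrix.
#' @param weights per-variant score weights (length = columns of genotypes).
#' @param target_r2 fraction of exposure variance explained by the score,
#'   in (0, 1].
#' @param confounder latent confounder vector (standard normal scale), or
#'   `NULL`.
#' @param confounder_effect loading of the confounder on the standardized
#'   exposure.
#' @param exposure_mean,exposure_sd natural-unit location and scale.
#' @param seed integer seed.
#' @return numeric exposure vector with attributes `score` (the raw allele
#'   score) and `exposure_z` (the standardized exposure).
#' @export
simulateExposure <- function(genotypes, weights, target_r2,
                             confounder = NULL, confounder_effect = 0,
                             exposure_mean = 0, exposure_sd = 1, seed = 1L) {
  if (ncol(genotypes) != length(weights))
    stop("weights length must equal the number of variants")
  if (target_r2 > 1 || target_r2 < 0)
    stop("target_r2 must lie in [0, 1]")
  if (is.null(confounder)) {
    confounder <- rep(0, nrow(genotypes))
    confounder_effect <- 0
  }
  if (target_r2 + confounder_effect^2 > 1)
    stop("target_r2 + confounder_effect^2 must not exceed 1")
  if (exposure_sd <= 0) stop("exposure_sd must be positive")
  n <- nrow(genotypes)
  score <- drop(genotypes %*% weights)
  s <- sd(score)
  sz <- if (is.finite(s) && s > 0) (score - mean(score)) / s else rep(0, n)
  set.seed(seed)
  resid_sd <- sqrt(max(0, 1 - target_r2 - confounder_effect^2))
  z <- sqrt(target_r2) * sz + confounder_effect * confounder +
    resid_sd * rnorm(n)
  exposure <- exposure_mean + exposure_sd * z
  attr(exposure, "score") <- score
  attr(exposure, "exposure_z") <- z
  exposure
}

#' Simulate a standardized protein panel with detection-limit flags
#'
#' Each protein is generated as
#' \eqn{P_k = \beta_k X_z + \gamma_k U + G\alpha_k + \lambda_k F + \sigma_k\epsilon},
#' with the residual scale chosen so each column has unit population variance
#' before censoring.  Values in the lowest `lod_quantile[k]` fraction of each
#' column are flagged below the limit of detection; flagged values are
#' retained (mirroring how proximity-extension assays report values below
#' LOD) and excluded downstream by [excludeLowDetect()].
#'
#' @param exposure_z standardized exposure vector.
#' @param confounder latent confounder vector.
#' @param genotypes dosage matrix for the same individuals (used only when
#'   the truth set carries nonzero pleiotropy).
#' @param truth a [TruthSet] holding effects `exposureEffect`,
#'   `confounderLoading`, `sharedFactorLoading`, and `pleiotropy`.
#' @param lod_quantile per-protein below-LOD fraction, each in [0, 1).
#' @param seed integer seed.
#' @return list with `npx` (n x K matrix), `belowLOD` (logical matrix), and
#'   `lod` (per-protein detection thresholds).
#' @export
simulateProteins <- function(exposure_z, confounder, genotypes, truth,
                             lod_quantile, seed = 1L) {
  beta <- truth@exposureEffect
  gamma <- truth@confounderLoading
  lambda <- truth@sharedFactorLoading
  alpha <- truth@pleiotropy
  k <- length(beta)
  n <- length(exposure_z)
  if (length(confounder) != n)
    stop("confounder must match exposure length")
  if (any(lod_quantile < 0 | lod_quantile >= 1))
    stop("lod_quantile entries must lie in [0, 1)")
  lod_quantile <- rep_len(lod_quantile, k)
  set.seed(seed)
  direct <- if (any(alpha != 0)) {
    if (nrow(genotypes) != n) stop("genotypes must match exposure length")
    genotypes %*% alpha
  } else matrix(0, n, k)
  # theoretical variance contributed by the pleiotropic genotype component
  gvar <- if (any(alpha != 0)) {
    colSums(alpha^2 * (2 * truth@mafs * (1 - truth@mafs)))
  } else rep(0, k)
  sys_var <- beta^2 + gamma^2 + lambda^2 + gvar
  if (any(sys_var >= 1))
    stop("systematic protein variance reaches 1; reduce effect loadings")
  f <- rnorm(n)
  eps <- matrix(rnorm(n * k), n, k)
  npx <- outer(exposure_z, beta) + outer(confounder, gamma) +
    outer(f, lambda) + direct +
    sweep(eps, 2, sqrt(1 - sys_var), `*`)
  colnames(npx) <- sprintf("prot%02d", seq_len(k))
  lod <- vapply(seq_len(k), function(j) {
    as.numeric(quantile(npx[, j], probs = lod_quantile[j]))
  }, numeric(1))
  below <- sweep(npx, 2, lod, `<`)
  list(npx = npx, belowLOD = below, lod = lod)
}

#' Simulate proportional-hazards event times
#'
#' Event times follow a Weibull (default exponential) baseline hazard scaled
#' by \eqn{\exp(x^T\beta)}.  Censoring combines the administrative horizon
#' with independent exponential dropout whose rate is chosen so the dropout
#' probability within follow-up equals `censor_rate`.
#'
#' @param covariates numeric matrix (or data.frame of numerics).
#' @param log_hrs per-covariate log hazard ratios.
#' @param followup_years administrative censoring horizon (> 0).
#' @param censor_rate dropout probability within follow-up, in [0, 1].
#' @param baseline_hazard events per year at covariate zero.
#' @param shape Weibull shape (1 = exponential).
#' @param seed integer seed.
#' @return data.frame with columns `time` (years, in (0, followup_years])
#'   and `event` (0/1).
#' @export
simulateSurvival <- function(covariates, log_hrs, followup_years,
                             censor_rate = 0, baseline_hazard = 0.0274,
                             shape = 1, seed = 1L) {
  covariates <- as.matrix(covariates)
  if (ncol(covariates) != length(log_hrs))
    stop("log_hrs length must equal the covariate count")
  if (followup_years <= 0) stop("followup_years must be positive")
  if (censor_rate < 0 || censor_rate > 1)
    stop("censor_rate must lie in [0, 1]")
  n <- nrow(covariates)
  set.seed(seed)
  eta <- drop(covariates %*% log_hrs)
  u <- runif(n)
  tev <- (-log(u) / (baseline_hazard * exp(eta)))^(1 / shape)
  cens <- if (censor_rate >= 1) {
    rep(0, n)
  } else if (censor_rate == 0) {
    rep(Inf, n)
  } else {
    rexp(n, rate = -log1p(-censor_rate) / followup_years)
  }
  time <- pmax(pmin(tev, cens, followup_years), 1e-12)
  event <- as.integer(tev <= pmin(cens, followup_years))
  data.frame(time = time, event = event)
}

#' Generate a full synthetic cohort study
#'
#' Assembles the nested design: a genotyped population sample with a
#' polygenic exposure, a simple-random-sample proteomics subcohort with a
#' standardized protein panel, baseline covariates (age, sex, region,
#' systolic blood pressure, diabetes, prevalent disease), and
#' proportional-hazards follow-up.  The exposure's association with the
#' event operates through the causal proteins, blood pressure and diabetes
#' plus a small direct term, so attenuation-based mediation has signal to
#' find, and a shared latent confounder drives exposure, proteins and hazard
#' so observational and genetic estimates diverge by design.
#'
#' @param config a [SimConfig].
#' @return a [CohortStudy]; its truth set is retrievable with [truthSet()].
#' @examples
#' study <- makeStudy(simConfigDefault(nGwas = 1500L, nSubcohort = 300L,
#'                                     nVariants = 30L, seed = 11L))
#' study
#' @export
makeStudy <- function(config) {
  methods::validObject(config)
  m <- config@nVariants
  k <- length(config@proteinEffects)
  n <- config@nGwas

  set.seed(seedFor(config@seed, "variants"))
  mafs <- runif(m, config@mafRange[1], config@mafRange[2])
  w <- rnorm(m)
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE), m, 2)
  swap <- alleles[, 1] == alleles[, 2]
  alleles[swap, 2] <- vapply(alleles[swap, 1], function(a) {
    sample(setdiff(c("A", "C", "G", "T"), a), 1)
  }, character(1))
  chrom <- sample(1:22, m, replace = TRUE)
  pos <- sample.int(240000000L, m, replace = TRUE)
  pleio <- if (config@pleiotropySD > 0 || config@pleiotropyMean != 0) {
    matrix(rnorm(m * k, config@pleiotropyMean, config@pleiotropySD), m, k)
  } else matrix(0, m, k)

  g <- simulateGenotypes(n, mafs, seed = seedFor(config@seed, "genotypes"))

  set.seed(seedFor(config@seed, "confounder"))
  u <- rnorm(n)

  exposure <- simulateExposure(
    g, w, config@varianceExplained, confounder = u,
    confounder_effect = config@confounderExposure,
    exposure_mean = config@exposureMean, exposure_sd = config@exposureSD,
    seed = seedFor(config@seed, "exposure"))
  exposure_z <- attr(exposure, "exposure_z")
  score <- attr(exposure, "score")

  # external weight table: true per-allele effect on the standardized
  # exposure, reported with a nominal SE as a summary-statistic source would
  s_score <- sd(score)
  per_allele <- if (s_score > 0) sqrt(config@varianceExplained) * w / s_score
                else rep(0, m)
  variants <- S4Vectors::DataFrame(
    id = sprintf("v%04d", seq_len(m)),
    chrom = chrom, pos = pos,
    effect_allele = alleles[, 1], other_allele = alleles[, 2],
    eaf = mafs,
    weight_beta = per_allele,
    weight_se = abs(per_allele) * 0.1 + 1e-4)

  set.seed(seedFor(config@seed, "covariates"))
  age <- rnorm(n, 52.2, 10.5)
  sex <- factor(ifelse(runif(n) < 0.613, "F", "M"), levels = c("F", "M"))
  region <- factor(sample(sprintf("R%d", 1:4), n, replace = TRUE))
  sbp_z <- 0.25 * exposure_z + sqrt(1 - 0.25^2) * rnorm(n)
  diabetes <- as.integer(runif(n) < plogis(-3.4 + 0.3 * exposure_z))
  prevalent <- as.integer(runif(n) < plogis(-2.7 + 0.3 * scale(age)[, 1] +
                                              0.2 * exposure_z))
  covariates <- S4Vectors::DataFrame(
    id = sprintf("id%06d", seq_len(n)),
    age = age, sex = sex, region = region,
    sbp_z = sbp_z, diabetes = diabetes, prevalent_cvd = prevalent,
    exposure = as.numeric(exposure), exposure_z = exposure_z,
    score = score, confounder = u)
  rownames(g) <- covariates$id

  truth <- new("TruthSet",
               exposureEffect = config@proteinEffects,
               confounderLoading = config@confounderProtein,
               sharedFactorLoading = config@proteinSharedFactor,
               pleiotropy = pleio,
               proteinLogHR = config@proteinLogHR,
               exposureLogHR = config@hazardExposure,
               confounderLogHR = config@hazardConfounder,
               scoreWeights = w,
               mafs = mafs,
               confounder = u)

  set.seed(seedFor(config@seed, "subcohort"))
  idx <- sort(sample.int(n, config@nSubcohort))

  prot <- simulateProteins(exposure_z[idx], u[idx], g[idx, , drop = FALSE],
                           truth, config@lodQuantile,
                           seed = seedFor(config@seed, "proteins"))

  age_z <- (age[idx] - mean(age)) / sd(age)
  surv_design <- cbind(age_z = age_z,
                       exposure_z = exposure_z[idx],
                       sbp_z = sbp_z[idx],
                       diabetes = diabetes[idx],
                       confounder = u[idx],
                       prot$npx)
  log_hrs <- c(config@hazardAge, config@hazardExposure, config@hazardSBP,
               config@hazardDiabetes, config@hazardConfounder,
               config@proteinLogHR)
  surv <- simulateSurvival(surv_design, log_hrs, config@followupYears,
                           censor_rate = config@censorRate,
                           baseline_hazard = config@baselineHazard,
                           shape = config@weibullShape,
                           seed = seedFor(config@seed, "survival"))

  cd <- covariates[idx, ]
  cd$time_years <- surv$time
  cd$event <- surv$event
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = t(prot$npx), belowLOD = t(prot$belowLOD)),
    rowData = S4Vectors::DataFrame(protein = colnames(prot$npx),
                                   lod = prot$lod,
                                   true_beta = truth@exposureEffect,
                                   true_log_hr = truth@proteinLogHR),
    colData = cd)
  colnames(se) <- cd$id

  new("CohortStudy", variants = variants, genotypes = g,
      covariates = covariates, subcohort = se, truth = truth,
      config = config)
}
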