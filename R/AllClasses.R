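#' Simulation configuration for a synthetic cohort study
#'
#' An S4 container holding every parameter of the synthetic-cohort generator.
#' The seed fully determines the generated study.  Defaults emulate the
#' design the analysis pipeline targets: a large genotyped population sample
#' with a polygenic adiposity exposure (score explaining ~2% of variance,
#' exposure SD 3.4 units), a randomly sampled proteomics subcohort of 628
#' with a 92-protein log-scale panel (two proteins almost entirely below the
#' assay detection limit, mirroring real panel attrition to 90 analyzable
#' proteins), one shared latent confounder, and proportional-hazards event
#' times over 10 years of follow-up.
#'
#' @slot nGwas integer, genotyped individuals (stage-1 sample).
#' @slot nSubcohort integer, subcohort with proteins and follow-up.
#' @slot nVariants integer, independent instrument variants.
#' @slot mafRange numeric(2), minor-allele-frequency range in (0, 0.5].
#' @slot varianceExplained fraction of exposure variance explained by the
#'   allele score (in expectation).
#' @slot exposureMean,exposureSD exposure location and scale on its natural
#'   unit (body-mass-index-like units).
#' @slot confounderExposure loading of the latent standard-normal confounder
#'   on the standardized exposure.
#' @slot proteinEffects numeric, per-protein causal effect of the exposure
#'   (SD protein per SD exposure).
#' @slot confounderProtein numeric, per-protein confounder loadings.
#' @slot proteinSharedFactor numeric, optional per-protein loading on a
#'   shared latent protein factor (induces inter-protein correlation).
#' @slot pleiotropyMean,pleiotropySD mean and SD of per-variant direct
#'   (horizontal-pleiotropic) effects on each protein; 0/0 disables.
#' @slot proteinLogHR numeric, per-protein log hazard ratio on the event.
#' @slot hazardExposure direct (non-protein-mediated) log HR per SD exposure.
#' @slot hazardConfounder log HR per unit latent confounder.
#' @slot hazardAge log HR per SD age.
#' @slot hazardSBP log HR per SD systolic blood pressure.
#' @slot hazardDiabetes log HR for diabetes at baseline.
#' @slot baselineHazard baseline event rate per year at covariate zero.
#' @slot weibullShape Weibull shape of the baseline hazard (1 = exponential).
#' @slot followupYears administrative censoring horizon in years.
#' @slot censorRate probability of random dropout within follow-up.
#' @slot lodQuantile numeric, per-protein fraction of values below the
#'   limit of detection.
#' @slot seed integer master seed; all stage seeds derive from it.
#' @export
setClass("SimConfig", representation(
  nGwas = "integer",
  nSubcohort = "integer",
  nVariants = "integer",
  mafRange = "numeric",
  varianceExplained = "numeric",
  exposureMean = "numeric",
  exposureSD = "numeric",
  confounderExposure = "numeric",
  proteinEffects = "numeric",
  confounderProtein = "numeric",
  proteinSharedFactor = "numeric",
  pleiotropyMean = "numeric",
  pleiotropySD = "numeric",
  proteinLogHR = "numeric",
  hazardExposure = "numeric",
  hazardConfounder = "numeric",
  hazardAge = "numeric",
  hazardSBP = "numeric",
  hazardDiabetes = "numeric",
  baselineHazard = "numeric",
  weibullShape = "numeric",
  followupYears = "numeric",
  censorRate = "numeric",
  lodQuantile = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  k <- length(object@proteinEffects)
  if (object@nGwas < 1L) msg <- c(msg, "nGwas must be positive")
  if (object@nSubcohort > object@nGwas)
    msg <- c(msg, "nSubcohort must not exceed nGwas")
  if (object@nVariants < 1L) msg <- c(msg, "nVariants must be positive")
  if (length(object@mafRange) != 2L ||
      any(object@mafRange <= 0) || any(object@mafRange > 0.5) ||
      object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be an increasing pair in (0, 0.5]")
  if (object@varianceExplained <= 0 || object@varianceExplained > 1)
    msg <- c(msg, "varianceExplained must be in (0, 1]")
  if (object@exposureSD <= 0) msg <- c(msg, "exposureSD must be positive")
  for (nm in c("confounderProtein", "proteinSharedFactor", "proteinLogHR",
               "lodQuantile")) {
    if (length(slot(object, nm)) != k)
      msg <- c(msg, sprintf("%s must have one value per protein", nm))
  }
  if (any(object@lodQuantile < 0 | object@lodQuantile >= 1))
    msg <- c(msg, "lodQuantile entries must lie in [0, 1)")
  if (object@censorRate < 0 || object@censorRate > 1)
    msg <- c(msg, "censorRate must lie in [0, 1]")
  if (object@followupYears <= 0) msg <- c(msg, "followupYears must be positive")
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be positive")
  if (object@weibullShape <= 0) msg <- c(msg, "weibullShape must be positive")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a generated cohort
#'
#' Stored alongside every synthetic study so downstream recovery tests can be
#' expressed against known quantities.
#'
#' @slot exposureEffect per-protein true causal effect (SD/SD).
#' @slot confounderLoading per-protein confounder loading.
#' @slot sharedFactorLoading per-protein shared-factor loading.
#' @slot pleiotropy nVariants x nProteins matrix of direct variant effects.
#' @slot proteinLogHR per-protein true log hazard ratio.
#' @slot exposureLogHR direct exposure log HR (not through proteins).
#' @slot confounderLogHR confounder log HR.
#' @slot scoreWeights per-variant generative weights.
#' @slot mafs per-variant minor-allele frequencies.
#' @slot confounder per-person latent confounder draws (genotyped sample).
#' @export
setClass("TruthSet", representation(
  exposureEffect = "numeric",
  confounderLoading = "numeric",
  sharedFactorLoading = "numeric",
  pleiotropy = "matrix",
  proteinLogHR = "numeric",
  exposureLogHR = "numeric",
  confounderLogHR = "numeric",
  scoreWeights = "numeric",
  mafs = "numeric",
  confounder = "numeric"
))

setValidity("TruthSet", function(object) {
  k <- length(object@exposureEffect)
  m <- length(object@scoreWeights)
  msg <- character()
  if (length(object@confounderLoading) != k)
    msg <- c(msg, "confounderLoading length must match exposureEffect")
  if (length(object@proteinLogHR) != k)
    msg <- c(msg, "proteinLogHR length must match exposureEffect")
  if (!all(dim(object@pleiotropy) == c(m, k)))
    msg <- c(msg, "pleiotropy must be nVariants x nProteins")
  if (length(object@mafs) != m)
    msg <- c(msg, "mafs length must match scoreWeights")
  if (length(msg)) msg else TRUE
})

#' A synthetic cohort study with nested proteomics subcohort
#'
#' The central data container: a large genotyped sample (dosage matrix plus
#' person-level covariates including the exposure) and a random subcohort
#' carried as a [SummarizedExperiment::SummarizedExperiment] whose assays are
#' the log-scale protein panel (`npx`) and its below-detection-limit flags
#' (`belowLOD`), with covariates and the time-to-event record in `colData`.
#'
#' @slot variants S4Vectors DataFrame describing the instrument variants
#'   (id, chrom, pos, alleles, eaf, external weight and SE).
#' @slot genotypes integer dosage matrix, individuals x variants.
#' @slot covariates DataFrame of person-level covariates for the genotyped
#'   sample (includes the exposure on natural and SD scale).
#' @slot subcohort SummarizedExperiment for the proteomics subcohort
#'   (proteins in rows, individuals in columns).
#' @slot truth the [TruthSet] used to generate the study.
#' @slot config the generating [SimConfig].
#' @export
setClass("CohortStudy", representation(
  variants = "DataFrame",
  genotypes = "matrix",
  covariates = "DataFrame",
  subcohort = "SummarizedExperiment",
  truth = "TruthSet",
  config = "SimConfig"
))

setValidity("CohortStudy", function(object) {
  msg <- character()
  if (nrow(object@genotypes) != nrow(object@covariates))
    msg <- c(msg, "genotypes and covariates disagree on sample size")
  if (ncol(object@genotypes) != nrow(object@variants))
    msg <- c(msg, "genotype columns must align to the variant table")
  if (!all(colnames(object@subcohort) %in% object@covariates$id))
    msg <- c(msg, "subcohort ids must be a subset of genotyped ids")
  if (length(msg)) msg else TRUE
})
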