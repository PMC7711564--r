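## Pipeline orchestration: simulate -> score -> observational -> MR ->
## survival/mediation -> meta/coloc, with per-stage substream seeds and a
## manifest sufficient to reproduce every table.

#' Per-variant simple-regression associations
#'
#' Vectorized per-variant OLS of a trait on each dosage column:
#' `beta = Sxy/Sxx`, `se = sqrt((Syy - beta Sxy)/(n-2)/Sxx)`.  Used to turn
#' individual-level data into summary statistics for the
#' summary-statistic MR estimators and for colocalization.
#'
#' @param genotypes dosage matrix.
#' @param y trait vector.
#' @return data.frame: id (column names), beta, se.
#' @export
perVariantAssoc <- function(genotypes, y) {
  n <- length(y)
  stopifnot(nrow(genotypes) == n, n > 2)
  gc_ <- sweep(genotypes, 2, colMeans(genotypes))
  yc <- y - mean(y)
  sxx <- colSums(gc_^2)
  sxy <- drop(crossprod(gc_, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  sse <- pmax(syy - beta * sxy, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  data.frame(id = colnames(genotypes) %||% sprintf("v%04d", seq_along(beta)),
             beta = beta, se = se, stringsAsFactors = FALSE)
}

#' Assemble a validated pipeline configuration
#'
#' @param sim a [SimConfig] describing the synthetic study (or `NULL` for
#'   the defaults of [simConfigDefault()] at the given seed).
#' @param fdr_q FDR level for the observational stage.
#' @param maf_threshold instrument MAF filter.
#' @param unweighted use the unweighted allele score.
#' @param cis_window bp window for the gene-proximity sensitivity filter.
#' @param gene_regions optional data.frame (chrom, start, end; 1-based) for
#'   the proximity filter.
#' @param external_estimates optional study-estimate data.frame or TSV path
#'   for the meta-analysis stage; `NULL` uses the packaged synthetic table.
#' @param coloc_trait protein to colocalize against the exposure (default:
#'   the first panel protein).
#' @param n_boot_wm weighted-median bootstrap replicates.
#' @param seed master seed; overrides the `sim` seed so one integer
#'   reproduces the whole run.
#' @return a validated `PipelineConfig` (list).
#' @export
pipelineConfig <- function(sim = NULL, fdr_q = 0.05, maf_threshold = 0.01,
                           unweighted = FALSE, cis_window = 1e6,
                           gene_regions = NULL, external_estimates = NULL,
                           coloc_trait = NULL, n_boot_wm = 1000L,
                           seed = 1L) {
  seed <- as.integer(seed)
  sim <- sim %||% simConfigDefault(seed = seed)
  sim@seed <- seed
  methods::validObject(sim)
  stopifnot(fdr_q > 0, fdr_q < 1, maf_threshold > 0, maf_threshold < 0.5,
            cis_window >= 0)
  if (is.character(external_estimates))
    external_estimates <- readStudyEstimates(external_estimates)
  structure(list(sim = sim, fdr_q = fdr_q, maf_threshold = maf_threshold,
                 unweighted = unweighted, cis_window = cis_window,
                 gene_regions = gene_regions,
                 external_estimates = external_estimates,
                 coloc_trait = coloc_trait,
                 n_boot_wm = as.integer(n_boot_wm), seed = seed),
            class = "PipelineConfig")
}

pipelineAdjustments <- function() {
  list(obs = adjustmentSet(c("age", "sex", "region", "sbp_z", "diabetes"),
                           "full"),
       mr = adjustmentSet(c("age", "sex", "region"), "genetic"),
       base = adjustmentSet(c("age", "sex", "region"), "base"))
}

#' Run the full triangulation pipeline on a synthetic study
#'
#' Executes the stages in dependency order — simulate, allele score and
#' instrument strength, observational panel associations with FDR control,
#' Mendelian randomization (split-sample 2SLS per protein plus
#' summary-statistic IVW / MR-Egger / weighted-median / Steiger), Cox
#' protein-event associations, attenuation mediation, meta-analysis with
#' external estimates, and exposure-protein colocalization — writing one
#' TSV per stage plus a JSON manifest into `out_dir`.  A failure in one
#' protein's model is logged and skipped, not fatal.  Reruns with the same
#' configuration are byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly; stage tables are also returned in the
#'   `"tables"` attribute.
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  adj <- pipelineAdjustments()
  tables <- list()

  ## serialized config, verbatim
  cfg_list <- list(
    seed = config$seed, fdr_q = config$fdr_q,
    maf_threshold = config$maf_threshold, unweighted = config$unweighted,
    cis_window = config$cis_window, n_boot_wm = config$n_boot_wm,
    sim = list(nGwas = config$sim@nGwas, nSubcohort = config$sim@nSubcohort,
               nVariants = config$sim@nVariants,
               varianceExplained = config$sim@varianceExplained,
               exposureSD = config$sim@exposureSD,
               followupYears = config$sim@followupYears,
               censorRate = config$sim@censorRate))
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))

  ## stage: simulate
  study <- makeStudy(config$sim)
  variants <- as.data.frame(variantTable(study))
  cov_full <- as.data.frame(covariateTable(study))
  se <- subcohortSE(study)
  cov_sub <- as.data.frame(SummarizedExperiment::colData(se))
  panel <- t(SummarizedExperiment::assay(se, "npx"))
  lod <- t(SummarizedExperiment::assay(se, "belowLOD"))
  writeTSV(variants, file.path(out_dir, "study_variants.tsv"))

  ## stage: allele score + instrument strength
  kept <- filterByMAF(variants, config$maf_threshold)
  gsub_ <- genotypeDosage(study)[, kept$id, drop = FALSE]
  score <- computeScore(gsub_, kept, weighted = !config$unweighted)
  cov_full$score_used <- score
  cov_sub$score_used <- score[match(cov_sub$id, cov_full$id)]
  strength <- instrumentStrength(score, cov_full$exposure,
                                 cov_full[, adj$mr$covariates])
  strength$score <- if (config$unweighted) "unweighted" else "weighted"
  strength$n_variants <- nrow(kept)
  tables$instrument <- strength
  writeTSV(strength, file.path(out_dir, "instrument.tsv"))

  ## stage: observational associations (panel z-scored, low-detect excluded)
  panel_kept <- excludeLowDetect(panel, lod, max_below_frac = 0.99)
  panel_z <- apply(panel_kept, 2, standardize)
  exclusion_log <- data.frame(protein = attr(panel_kept, "excluded"),
                              reason = "below LOD in > 99% of samples")
  writeTSV(exclusion_log, file.path(out_dir, "panel_exclusions.tsv"))
  cov_sub$exposure_sdz <- standardize(cov_sub$exposure)
  obs <- panelExposureAssoc(panel_z, cov_sub, "exposure_sdz", adj$obs,
                            fdr_q = config$fdr_q)
  tables$observational <- obs
  writeTSV(obs, file.path(out_dir, "observational.tsv"))
  rb <- renyiBand(obs$p, q = config$fdr_q)
  writeTSV(rb$data, file.path(out_dir, "renyi.tsv"))

  ## stage: MR (2SLS per protein, per 1-SD exposure)
  tag <- if (config$unweighted) "unweighted" else "weighted"
  tsls <- lapply(colnames(panel_z), function(tr) {
    d2 <- cbind(cov_sub, .prot = panel_z[, tr])
    r <- tryCatch(suppressWarnings(
      twoStageLeastSquares(cov_full, d2, "score_used", "exposure", ".prot",
                           covariates1 = adj$mr$covariates)),
      error = function(e) NULL)
    if (is.null(r)) return(NULL)
    r <- rescalePerExposureSD(r, config$sim@exposureSD)
    cbind(trait = tr, r, score = tag)
  })
  tsls <- do.call(rbind, tsls)
  tables$mr_tsls <- tsls
  writeTSV(tsls, file.path(out_dir, "mr_tsls.tsv"))

  ## stage: summary-statistic MR per protein
  gvar <- gsub_
  exp_stats <- perVariantAssoc(gvar, standardize(cov_full$exposure))
  gvar_sub <- gvar[match(cov_sub$id, cov_full$id), , drop = FALSE]
  r2_exp <- strength$r2
  mr_sum <- lapply(colnames(panel_z), function(tr) {
    out_stats <- perVariantAssoc(gvar_sub, panel_z[, tr])
    assocs <- data.frame(beta_exposure = exp_stats$beta,
                         se_exposure = exp_stats$se,
                         beta_outcome = out_stats$beta,
                         se_outcome = out_stats$se)
    rows <- tryCatch({
      ivw <- mrIVW(assocs)
      egg <- mrEgger(assocs)
      wm <- mrWeightedMedian(assocs, n_boot = config$n_boot_wm,
                             seed = seedFor(config$seed, paste0("wm_", tr)))
      base <- c("method", "estimate", "se", "ci_low", "ci_high", "p",
                "n_variants")
      r <- rbind(ivw[base], egg[base], wm[base])
      r$egger_intercept <- c(NA, egg$egger_intercept, NA)
      r$intercept_se <- c(NA, egg$intercept_se, NA)
      st <- steigerDirection(r2_exp, nrow(cov_full),
                             summary(lm(panel_z[, tr] ~
                                          cov_sub$score_used))$r.squared,
                             nrow(cov_sub))
      r$steiger_orientation <- st$orientation
      r$steiger_p <- st$p
      cbind(trait = tr, r)
    }, error = function(e) NULL)
    rows
  })
  mr_sum <- do.call(rbind, mr_sum)
  tables$mr_summary <- mr_sum
  writeTSV(mr_sum, file.path(out_dir, "mr_summary.tsv"))

  ## stage: protein -> event Cox associations
  surv <- proteinCvdAssoc(panel_kept, cov_sub, adj$obs,
                          exclude_prevalent = TRUE)
  tables$survival <- surv
  writeTSV(surv, file.path(out_dir, "survival.tsv"))

  ## stage: attenuation mediation
  med_proteins <- surv$trait[surv$p < 0.05]
  att_data <- cbind(cov_sub, panel_z)
  att_data <- att_data[att_data$prevalent_cvd == 0, ]
  att_rows <- list()
  base_covs <- adj$base$covariates
  if (length(med_proteins)) {
    att_rows$proteins <- attenuation(att_data, "exposure_z", base_covs,
                                     med_proteins,
                                     mediator_set = "proteins")
  }
  att_rows$sbp <- attenuation(att_data, "exposure_z", base_covs, "sbp_z",
                              mediator_set = "sbp")
  att_rows$diabetes <- attenuation(att_data, "exposure_z", base_covs,
                                   "diabetes", mediator_set = "diabetes")
  att_rows$joint <- attenuation(att_data, "exposure_z", base_covs,
                                c(med_proteins, "sbp_z", "diabetes"),
                                mediator_set = "proteins+sbp+diabetes")
  att <- do.call(rbind, att_rows)
  tables$attenuation <- att
  writeTSV(att, file.path(out_dir, "attenuation.tsv"))

  ## stage: meta-analysis with external estimates
  ext <- config$external_estimates %||% readStudyEstimates(
    system.file("extdata", "external_estimates_synthetic.tsv",
                package = "adipoMR", mustWork = TRUE))
  meta_rows <- list()
  for (tr in unique(ext$trait)) {
    own <- tsls[tsls$trait == tr, ]
    if (nrow(own) == 0) next
    est <- rbind(data.frame(study = "this_cohort", estimate = own$estimate,
                            se = own$se, ci_low = NA, ci_high = NA,
                            scale = "linear", level = 0.95),
                 data.frame(study = ext$study[ext$trait == tr],
                            estimate = ext$estimate[ext$trait == tr],
                            se = if ("se" %in% names(ext))
                              ext$se[ext$trait == tr] else NA,
                            ci_low = ext$ci_low[ext$trait == tr],
                            ci_high = ext$ci_high[ext$trait == tr],
                            scale = ext$scale[ext$trait == tr],
                            level = 0.95))
    fx <- metaFixed(est)
    rd <- if (nrow(est) > 1) metaRandom(est) else NULL
    meta_rows[[tr]] <- cbind(trait = tr, rbind(fx, rd))
  }
  meta <- do.call(rbind, meta_rows)
  tables$meta <- meta
  writeTSV(meta, file.path(out_dir, "meta.tsv"))

  ## stage: exposure-protein colocalization at the instrument locus
  coloc_trait <- config$coloc_trait %||% colnames(panel_z)[1]
  out_stats <- perVariantAssoc(gvar_sub, panel_z[, coloc_trait])
  cl <- colocAbf(exp_stats, out_stats)
  cl <- cbind(trait = coloc_trait, cl)
  tables$coloc <- cl
  writeTSV(cl, file.path(out_dir, "coloc.tsv"))

  ## manifest: everything needed to reproduce the run bit-for-bit
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    package = "adipoMR",
    package_version = as.character(utils::packageVersion("adipoMR")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  out <- out_dir
  attr(out, "tables") <- tables
  invisible(out)
}

#' Triangulation consistency report
#'
#' Joins the observational, genetic (2SLS) and survival stage tables of a
#' pipeline run into one per-protein table: observational beta, genetic
#' beta, the Cochran Q p-value comparing them, the protein-event hazard
#' ratio, and a direction-concordance flag (observational and genetic
#' effects agree in sign, and that sign matches the sign of the protein's
#' log hazard ratio).  Missing stages yield a partial report with explicit
#' NA columns.
#'
#' @param run_dir a directory written by [runPipeline()].
#' @return the consistency data.frame (also written as
#'   `triangulation.tsv`).
#' @export
triangulationReport <- function(run_dir) {
  path <- function(f) file.path(run_dir, f)
  if (!file.exists(path("observational.tsv")))
    stop("observational table missing from ", run_dir)
  obs <- readTSV(path("observational.tsv"))
  out <- data.frame(trait = obs$trait, obs_beta = obs$beta, obs_se = obs$se,
                    stringsAsFactors = FALSE)
  if (file.exists(path("mr_tsls.tsv"))) {
    mr <- readTSV(path("mr_tsls.tsv"))
    i <- match(out$trait, mr$trait)
    out$mr_beta <- mr$estimate[i]
    out$mr_se <- mr$se[i]
    qp <- mapply(function(b1, s1, b2, s2) {
      if (anyNA(c(b1, s1, b2, s2))) return(NA_real_)
      cochranQTwoEstimates(b1, s1, b2, s2)$p
    }, out$obs_beta, out$obs_se, out$mr_beta, out$mr_se)
    out$cochran_q_p <- qp
  } else {
    message("MR table missing: genetic columns left empty")
    out$mr_beta <- out$mr_se <- out$cochran_q_p <- NA_real_
  }
  if (file.exists(path("survival.tsv"))) {
    sv <- readTSV(path("survival.tsv"))
    i <- match(out$trait, sv$trait)
    out$hr <- sv$hr[i]
    out$log_hr <- sv$log_hr[i]
  } else {
    message("survival table missing: hazard columns left empty")
    out$hr <- out$log_hr <- NA_real_
  }
  out$direction_concordant <- with(out, ifelse(
    is.na(mr_beta) | is.na(log_hr), NA,
    sign(obs_beta) == sign(mr_beta) & sign(mr_beta) == sign(log_hr)))
  writeTSV(out, file.path(run_dir, "triangulation.tsv"))
  out
}
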