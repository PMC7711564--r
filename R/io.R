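## Tab-separated exchange formats for study inputs and outputs.

writeTSV <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

readTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a cohort study as tab-separated tables
#'
#' One table per entity: `variants.tsv`, `genotypes.tsv` (dosage layout,
#' individuals in rows), `covariates.tsv`, `proteins.tsv`, `lod_flags.tsv`,
#' `survival.tsv`, and the truth set (`truth_proteins.tsv`,
#' `truth_variants.tsv`).
#'
#' @param study a [CohortStudy].
#' @param dir output directory (created if absent).
#' @param genotypes write the (large) dosage table too.
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir, genotypes = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTSV(variantTable(study), file.path(dir, "variants.tsv"))
  writeTSV(covariateTable(study), file.path(dir, "covariates.tsv"))
  if (genotypes) {
    g <- as.data.frame(genotypeDosage(study))
    g <- cbind(id = covariateTable(study)$id, g)
    writeTSV(g, file.path(dir, "genotypes.tsv"))
  }
  se <- subcohortSE(study)
  npx <- as.data.frame(t(SummarizedExperiment::assay(se, "npx")))
  writeTSV(cbind(id = colnames(se), npx), file.path(dir, "proteins.tsv"))
  lod <- as.data.frame(t(SummarizedExperiment::assay(se, "belowLOD")))
  writeTSV(cbind(id = colnames(se), lod), file.path(dir, "lod_flags.tsv"))
  cd <- SummarizedExperiment::colData(se)
  writeTSV(data.frame(id = cd$id, time_years = cd$time_years,
                      event = cd$event, prevalent_cvd = cd$prevalent_cvd),
           file.path(dir, "survival.tsv"))
  truth <- truthSet(study)
  writeTSV(data.frame(protein = rownames(se),
                      true_beta = truth@exposureEffect,
                      confounder_loading = truth@confounderLoading,
                      true_log_hr = truth@proteinLogHR),
           file.path(dir, "truth_proteins.tsv"))
  writeTSV(data.frame(id = variantTable(study)$id,
                      weight = truth@scoreWeights, maf = truth@mafs),
           file.path(dir, "truth_variants.tsv"))
  invisible(dir)
}

#' Export genotypes as a minimal VCF
#'
#' Writes an unphased GT-only VCF (one sample column per individual) for the
#' study's instrument variants.
#'
#' @param study a [CohortStudy].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportVCF <- function(study, path) {
  v <- as.data.frame(variantTable(study))
  g <- genotypeDosage(study)
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g)), collapse = "\t")),
             con)
  for (j in seq_len(nrow(v))) {
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$other_allele[j],
                       v$effect_allele[j], ".", "PASS", ".", "GT",
                       gt[g[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GWAS summary-statistic weight table
#'
#' Expects a TSV with header `SNP, CHR, POS, EA, OA, EAF, BETA, SE`; returns
#' a data.frame with the package's standard variant columns.
#'
#' @param path TSV path.
#' @return data.frame with columns id, chrom, pos, effect_allele,
#'   other_allele, eaf, weight_beta, weight_se.
#' @export
readWeightTable <- function(path) {
  x <- readTSV(path)
  need <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE")
  if (!all(need %in% names(x)))
    stop("weight table must have columns: ", paste(need, collapse = ", "))
  data.frame(id = x$SNP, chrom = x$CHR, pos = x$POS,
             effect_allele = x$EA, other_allele = x$OA, eaf = x$EAF,
             weight_beta = x$BETA, weight_se = x$SE,
             stringsAsFactors = FALSE)
}

#' Read a two-trait summary-statistic exchange table
#'
#' TSV with header `SNP, EA, OA, EAF, BETA_EXP, SE_EXP, BETA_OUT, SE_OUT`.
#'
#' @param path TSV path.
#' @return data.frame with columns id, effect_allele, other_allele, eaf,
#'   beta_exposure, se_exposure, beta_outcome, se_outcome.
#' @export
readSummaryStats <- function(path) {
  x <- readTSV(path)
  need <- c("SNP", "EA", "OA", "EAF", "BETA_EXP", "SE_EXP", "BETA_OUT",
            "SE_OUT")
  if (!all(need %in% names(x)))
    stop("summary-stat table must have columns: ",
         paste(need, collapse = ", "))
  data.frame(id = x$SNP, effect_allele = x$EA, other_allele = x$OA,
             eaf = x$EAF, beta_exposure = x$BETA_EXP,
             se_exposure = x$SE_EXP, beta_outcome = x$BETA_OUT,
             se_outcome = x$SE_OUT, stringsAsFactors = FALSE)
}

#' Read gene regions from a BED-like table
#'
#' Three-column BED (chrom, start, end; 0-based half-open), converted
#' internally to 1-based closed coordinates.
#'
#' @param path BED path (no header).
#' @return data.frame with columns chrom, start, end (1-based closed).
#' @export
readGeneRegionsBed <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(x[[1]]), start = x[[2]] + 1L, end = x[[3]],
             stringsAsFactors = FALSE)
}

#' Read a table of external study estimates for meta-analysis
#'
#' TSV mirroring the study-estimate contract: columns `study`, `trait`,
#' `estimate`, `scale` (`linear` or `log`), and either `se` or
#' `ci_low`/`ci_high` (with optional `level`, default 0.95).
#'
#' @param path TSV path.
#' @return data.frame of study estimates.
#' @export
readStudyEstimates <- function(path) {
  x <- readTSV(path)
  need <- c("study", "trait", "estimate", "scale")
  if (!all(need %in% names(x)))
    stop("study-estimate table must have columns: ",
         paste(need, collapse = ", "))
  x
}
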