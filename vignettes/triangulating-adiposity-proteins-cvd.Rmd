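---
title: "Triangulating adiposity, circulating proteins and cardiovascular disease"
author: "adipoMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating adiposity, circulating proteins and cardiovascular disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoMR)
```

## The scientific problem

Adiposity raises the risk of cardiovascular disease (CVD), and circulating
proteins — interleukins, chemokines, growth factors — are plausible
intermediates.  Three complementary designs can be brought to bear in one
cohort:

1. **Observational**: covariate-adjusted linear regression of each
   standardized protein on standardized adiposity;
2. **Genetic (Mendelian randomization, MR)**: a weighted allele score built
   from external genome-wide association study (GWAS) weights instruments
   adiposity, and split-sample two-stage least squares (2SLS) estimates the
   causal effect of adiposity on each protein, with summary-statistic
   estimators (IVW, MR-Egger, weighted median, Steiger) as sensitivity
   analyses;
3. **Prospective**: Cox proportional-hazards models relate each protein to
   incident vascular events, and attenuation of the adiposity-CVD hazard
   ratio after adjusting for putative mediators quantifies mediation.

When all three designs point the same way for a protein — adiposity shifts
the protein both observationally and genetically, and the protein predicts
incident disease — the triangulated evidence is much stronger than any one
design alone.  `runPipeline()` orchestrates exactly this sequence and
`triangulationReport()` tabulates the concordance.

Individual-level cohort data of this kind (biobank genotypes, Olink-style
proteomics, adjudicated follow-up) are access-restricted, so the package
ships a synthetic-cohort generator with a serialized ground truth
(`TruthSet`), making every downstream stage testable.

## The models

### Synthetic cohort

The generator draws, for `nGwas` individuals:

- **Genotypes**: unlinked biallelic variants, dosages
  $g_{ij} \sim \mathrm{Binomial}(2, p_j)$, hence Hardy–Weinberg
  proportions.  Linkage disequilibrium is deliberately absent: the method
  assumes an LD-pruned instrument set, so independence is the intended
  structure, not a shortcut.
- **Exposure**: with standardized allele score $S_z$ and one latent
  standard-normal confounder $U$,
  $$X_z = \sqrt{r^2}\,S_z + c\,U + \sqrt{1 - r^2 - c^2}\,\varepsilon,$$
  then $X = \mu + \sigma X_z$.  The score therefore explains $r^2$ of
  exposure variance in expectation; the default $r^2 = 0.0206$ and
  $\sigma = 3.4$ (body-mass-index-like units) put the instrument in the
  strong-instrument regime ($F \approx 1600$ at $n = 75{,}736$) and
  exercise the per-unit/per-SD rescaling logic.
- **Proteins** (subcohort only): for protein $k$,
  $$P_k = \beta_k X_z + \gamma_k U + G\alpha_k + \lambda_k F +
  \sigma_k \epsilon,$$
  with $\sigma_k$ chosen for unit population variance before censoring.
  $\beta_k$ is the causal effect of interest, $\gamma_k$ confounds the
  observational estimate (the default $\gamma_k = 0.25$ with exposure
  loading $c = 0.3$ biases ordinary least squares upward by
  $\gamma_k c \approx 0.075$ SD, so observational and MR estimates diverge
  by design), $\alpha_k$ is optional horizontal pleiotropy, and $F$ an
  optional shared protein factor.  Values in the lowest `lodQuantile`
  fraction of each protein are flagged below the limit of detection (LOD)
  but retained, mirroring how proximity-extension assays report below-LOD
  values; exclusion happens downstream via the >99% rule.
- **Follow-up** (subcohort only): event times from a Weibull
  (default exponential) baseline scaled by
  $\exp(x^\top\beta)$, administrative censoring at `followupYears`, and
  independent exponential dropout whose within-window probability is
  `censorRate`.  The exposure reaches the hazard through the causal
  proteins, systolic blood pressure and diabetes plus a small direct term,
  so attenuation-based mediation has real signal.

### Defaults as study conditions

The default `simConfigDefault()` describes one fixed reference study: a
628-person subcohort nested in a genotyped population sample; a 92-protein
log-scale panel of which 2 proteins are ~99.5% below LOD (leaving 90
analyzable), 30 carry nonzero exposure effects (0.35, 0.2, −0.2, 0.15 SD/SD
in blocks), and 10 carry nonzero log hazard ratios (0.17–0.34 in magnitude,
both directions); follow-up 10 years with ~25% cumulative incidence and 10%
dropout.  These were set once, from the study design the package emulates,
and are not tuned per analysis.

One deliberate scale choice: the reference genotyped sample defaults to
`nGwas = 20000` with 100 variants rather than the tens of thousands of
individuals times hundreds of variants of a real biobank, because a dosage
matrix of that size adds nothing statistically to the properties the
package demonstrates; analyses that specifically need the
population-sample size (instrument-strength calibration) generate the
larger sample on the fly with a small variant count.

### Genetic score and instrument strength

`computeScore()` is the weighted sum of effect-allele dosages
($\sum_j w_j g_{ij}$; unweighted: $w_j = 1$), with per-variant
mean-imputation of missing dosages.  `filterByMAF()` applies the minor
allele frequency cutoff (default 1%).  `instrumentStrength()` reports the
incremental $r^2$ of the score after covariates and the partial $F$; for a
single score without covariates this is the textbook identity
$F = r^2(n-2)/(1-r^2)$.  Whether the original analysis computed $F$ with
or without covariate adjustment is ambiguous; both are available and the
partial (adjusted) $F$ is the default.

### Mendelian randomization

`twoStageLeastSquares()` implements the split-sample estimator: stage 1
regresses the exposure on the score (plus covariates) in the large sample;
stage 2 regresses the outcome on the exposure predicted from stage-1
coefficients (plus covariates) in the subcohort.  The reported SE is the
model-based stage-2 SE, ignoring first-stage sampling error — defensible
because the stage-1 sample (~tens of thousands) dwarfs stage 2 (hundreds);
a two-stage nonparametric bootstrap (`n_boot`) is provided as a check.
With a single instrument and no covariates, 2SLS, the Wald ratio and IVW
coincide to numerical precision, which the tests assert.

The summary-statistic estimators follow their standard definitions: IVW is
the fixed-effect inverse-variance mean of Wald ratios (first-order delta
SEs); MR-Egger regresses outcome on exposure betas with an intercept
(exposure betas oriented positive; SEs on the multiplicative
random-effects convention with residual $\sigma$ floored at 1); the
weighted median interpolates the 50% crossing of the weight-cumulative
ratio distribution, with a parametric bootstrap SE (default 1,000 draws,
seeded); Steiger compares Fisher-transformed instrument correlations.
Harmonization matches on id plus alleles, flips on allele swaps, and drops
palindromic variants with allele frequency in (0.42, 0.58).
`excludeNearbyVariants()` drops instruments whose distance to the nearest
gene-span edge is at most the window (strictly: a variant exactly
1,000,001 bp away survives a 1 Mbp window), computed on `GenomicRanges`.

### Survival and mediation

`fitCox()` delegates partial-likelihood maximization to
`survival::coxph()` with Efron tie handling — tied event times are
expected at year-level granularity — and the tests verify it against a
brute-force grid maximization of an independently coded Efron partial
likelihood on small fixtures.  The time axis is follow-up time from
baseline.  The subcohort is a simple random sample, so unweighted Cox
within it is correct; weighted case-cohort estimators are out of scope.
`attenuation()` fits the Cox model with and without mediators and reports
$100(\beta_\text{base}-\beta_\text{adj})/\beta_\text{base}$ on the log-HR
scale (primary; an HR-scale variant attenuates the excess hazard
$HR - 1$), refusing a percentage when the base association is
indistinguishable from zero.  Attenuation components are deliberately
non-additive — the joint percentage is reported alongside the components,
never reconciled.

### Meta-analysis and colocalization

`metaFixed()`/`metaRandom()` wrap `metafor::rma.uni` (fixed-effect and
DerSimonian–Laird), after `seFromCI()` converts published intervals to
SEs; ratio measures (HR/RR/OR) pool on the log scale, and mixing scales is
an error rather than a silent merge.  The fixed-effect model is the
headline default, with both emitted side by side.  `colocAbf()` is the
single-causal-variant Wakefield approximate-Bayes-factor method with
canonical priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and prior
effect SD 0.15 (quantitative) or 0.2 (log-odds), all configurable, since
no installed package provides it; posteriors are computed on the log scale
with a log-sum-exp to keep PP0–PP4 normalized to $1 \pm 10^{-9}$.

## Numerical choices and degenerate inputs

- All 95% intervals use $z = 1.959964$.
- `simulateExposure()` accepts `target_r2 = 1` (exposure an affine
  function of the score) but rejects values above 1; a zero-variance score
  (all-zero weights) contributes nothing and the realized $r^2$ is ~0.
- `censorRate` maps to an independent exponential dropout rate
  $-\log(1-\text{censorRate})/\text{followup}$; `censorRate = 1` censors
  everyone immediately (times floored at $10^{-12}$ to keep them
  positive), which is the only way "probability 1 of dropout" and truly
  independent censoring coexist.
- Rank-deficient regression designs are rejected naming the collinear
  columns; constant scores are rejected (undefined $F$); Cox fits with no
  events or non-positive times are rejected; separation surfaces as a
  monotone-likelihood warning.
- Per-protein model failures inside panel loops are logged and skipped so
  a 90-trait panel cannot die on one degenerate trait.
- Determinism: every stage seed derives from one master seed through
  labeled substreams, so stages rerun in any order reproduce bit-identical
  tables; the run manifest records file checksums.

## What the tests do and do not show

The synthetic generator reproduces the *statistical* structure the
analysis assumes — HWE genotypes, calibrated instrument strength, a single
latent confounder, proportional hazards, below-LOD censoring — so passing
tests demonstrate that the estimators recover known truths under that
structure at realistic sizes (e.g. 2SLS coverage 93–97% at stage-1
$n = 50{,}000$ over 400 replicates while OLS is biased upward by >0.2 SD).
They do not demonstrate robustness to features the generator omits:
linkage disequilibrium between instruments, population stratification,
assay batch effects, non-proportional hazards, informative censoring, or
the real (unknown) correlation structure among 90 proteins beyond the
optional single shared factor, for which no canonical value is claimed.
Problem sizes in the test suite (replicate counts of 100–1,000; cohort
sizes of a few hundred to 50,000) were chosen as the smallest sizes at
which the distributional claims are sharp.

## Worked example

```{r example, eval = FALSE}
library(adipoMR)
cfg <- pipelineConfig(seed = 101L)
run <- runPipeline(cfg, "run_synthetic")
report <- triangulationReport("run_synthetic")
head(report[order(report$cochran_q_p), ])
```

The run directory contains one TSV per stage (`observational.tsv`,
`mr_tsls.tsv`, `mr_summary.tsv`, `survival.tsv`, `attenuation.tsv`,
`meta.tsv`, `coloc.tsv`), the instrument diagnostics, the serialized
configuration and a checksum manifest.  The README shows the printed
output of a complete small run.

## Known limitations

- 2SLS SEs ignore first-stage uncertainty (bootstrap available).
- The ordered-p-value band (`renyiBand()`) defaults to a BH-equivalent
  band and is an explicit approximation to more specialized
  ordered-statistic constructions.
- The meta-analysis stage pools published ratio measures (HR/OR/RR) on a
  common log scale; that scale merge mirrors common practice but is
  flagged in output rather than hidden.
- Colocalization assumes at most one causal variant per trait at the
  locus; fine-mapping-aware extensions are out of scope.
- Proxy-variant lookup, LD clumping, genotype QC and imputation are out of
  scope: inputs are assumed analysis-ready.
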