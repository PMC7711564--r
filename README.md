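# adipoMR

Triangulating adiposity, circulating protein biomarkers, and incident
cardiovascular disease (CVD) in cohort data.

Adiposity raises CVD risk; circulating proteins — interleukins, chemokines,
growth factors — are candidate intermediates. `adipoMR` implements the three
complementary designs that, taken together, triangulate such a pathway in a
single cohort, plus a synthetic-cohort generator (with serialized ground
truth) so the whole analysis is testable without access-restricted
individual-level biobank data:

1. **Observational**: covariate-adjusted linear regression of each
   standardized protein on standardized adiposity, under Benjamini–Hochberg
   false-discovery-rate control
   (`adjustedLinearAssoc`, `panelExposureAssoc`, `bhFdr`, `renyiBand`);
2. **Genetic (Mendelian randomization)**: a weighted allele score
   `S_i = Σ_j w_j g_ij` built from external GWAS weights
   (`computeScore`, `filterByMAF`, `instrumentStrength`; the partial-F
   identity `F = r²(n−2)/(1−r²)` holds for a single unadjusted score),
   split-sample two-stage least squares (`twoStageLeastSquares`), and the
   summary-statistic sensitivity estimators — inverse-variance weighting,
   MR-Egger, weighted median, Steiger directionality, Cochran Q, and
   gene-proximity instrument exclusion (`mrIVW`, `mrEgger`,
   `mrWeightedMedian`, `steigerDirection`, `cochranQTwoEstimates`,
   `excludeNearbyVariants`);
3. **Prospective**: Cox proportional-hazards associations of proteins with
   incident events and attenuation-based mediation
   `100·(β_base − β_adj)/β_base` of the adiposity–CVD log hazard ratio
   (`fitCox`, `proteinCvdAssoc`, `attenuation`);

with inverse-variance meta-analysis against external study estimates
(`metaFixed`, `metaRandom`, `seFromCI`) and single-causal-variant
approximate-Bayes-factor colocalization (`colocAbf`) to integrate published
evidence.

`runPipeline()` orchestrates all stages from one seeded configuration and
`triangulationReport()` tabulates per-protein direction concordance. The
methods vignette (`vignettes/triangulating-adiposity-proteins-cvd.Rmd`)
documents the models, defaults, and limitations.

## Worked example

```r
library(adipoMR)
study <- makeStudy(simConfigDefault(seed = 11L))
study
#> CohortStudy
#>   genotyped sample: 20000 individuals x 100 variants
#>   subcohort: 628 individuals x 92 proteins (197 events)
#>   seed: 11

run <- runPipeline(pipelineConfig(seed = 11L), "readme_run")
read.delim("readme_run/instrument.tsv")[, c("f_statistic", "r2", "n")]
#>   f_statistic      r2     n
#> 1       379.3 0.01861 20000

tr <- triangulationReport("readme_run")
head(tr[order(tr$cochran_q_p),
        c("trait", "obs_beta", "mr_beta", "cochran_q_p", "hr",
          "direction_concordant")], 5)
#>     trait obs_beta mr_beta cochran_q_p   hr direction_concordant
#> 16 prot16   0.2432  -0.676     0.00190 1.18                FALSE
#> 84 prot84   0.0890  -0.800     0.00268 1.20                FALSE
#> 10 prot10   0.4578  -0.230     0.02060 1.85                FALSE
#> 88 prot88   0.0876  -0.540     0.03423 1.28                FALSE
#> 62 prot62   0.0557   0.678     0.03591 1.06                 TRUE
```

Reading the output: the allele score explains ~1.9% of exposure variance in
the 20,000-person genotyped sample (partial F ≈ 379 — a strong instrument).
The report sorts proteins by the Cochran Q p-value comparing the
observational and genetic estimates: the top rows are proteins whose
genetic estimate is directionally opposite to the (confounded)
observational one, so they are flagged discordant; `hr` is the protein's
hazard ratio for incident events per 1-SD protein. The attenuation table
(`readme_run/attenuation.tsv`) reports how much of the adiposity–event log
hazard ratio is explained away by simultaneously adjusting for the
event-associated proteins, blood pressure, and diabetes — the components
are intentionally non-additive.

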