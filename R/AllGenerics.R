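#' @rdname CohortStudy-class
#' @param x a `CohortStudy`.
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname CohortStudy-class
#' @export
setGeneric("genotypeDosage", function(x) standardGeneric("genotypeDosage"))

#' @rdname CohortStudy-class
#' @export
setGeneric("covariateTable", function(x) standardGeneric("covariateTable"))

#' @rdname CohortStudy-class
#' @export
setGeneric("subcohortSE", function(x) standardGeneric("subcohortSE"))

#' @rdname CohortStudy-class
#' @export
setGeneric("truthSet", function(x) standardGeneric("truthSet"))

#' @rdname CohortStudy-class
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' @rdname CohortStudy-class
#' @export
setMethod("variantTable", "CohortStudy", function(x) x@variants)

#' @rdname CohortStudy-class
#' @export
setMethod("genotypeDosage", "CohortStudy", function(x) x@genotypes)

#' @rdname CohortStudy-class
#' @export
setMethod("covariateTable", "CohortStudy", function(x) x@covariates)

#' @rdname CohortStudy-class
#' @export
setMethod("subcohortSE", "CohortStudy", function(x) x@subcohort)

#' @rdname CohortStudy-class
#' @export
setMethod("truthSet", "CohortStudy", function(x) x@truth)

#' @rdname CohortStudy-class
#' @export
setMethod("simConfig", "CohortStudy", function(x) x@config)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  genotyped n: %d; subcohort n: %d; variants: %d\n",
              object@nGwas, object@nSubcohort, object@nVariants))
  cat(sprintf("  score variance explained: %.4f; exposure SD: %.2f\n",
              object@varianceExplained, object@exposureSD))
  cat(sprintf("  proteins: %d (%d with nonzero exposure effect)\n",
              length(object@proteinEffects), sum(object@proteinEffects != 0)))
  cat(sprintf("  follow-up: %.1f y; dropout probability: %.2f; seed: %d\n",
              object@followupYears, object@censorRate, object@seed))
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet\n")
  cat(sprintf("  %d proteins (%d causal), %d variants\n",
              length(object@exposureEffect), sum(object@exposureEffect != 0),
              length(object@scoreWeights)))
  cat(sprintf("  direct exposure log HR: %.3f; confounder log HR: %.3f\n",
              object@exposureLogHR, object@confounderLogHR))
})

setMethod("show", "CohortStudy", function(object) {
  cat("CohortStudy\n")
  cat(sprintf("  genotyped sample: %d individuals x %d variants\n",
              nrow(object@genotypes), ncol(object@genotypes)))
  cat(sprintf("  subcohort: %d individuals x %d proteins (%d events)\n",
              ncol(object@subcohort), nrow(object@subcohort),
              sum(SummarizedExperiment::colData(object@subcohort)$event)))
  cat(sprintf("  seed: %d\n", object@config@seed))
})
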