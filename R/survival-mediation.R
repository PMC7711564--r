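#' Fit a Cox proportional-hazards model
#'
#' Maximizes the partial likelihood with Efron handling of tied event times
#' (via the survival package's Newton-Raphson fitter) and returns a tidy
#' per-covariate table of log hazard ratios.  Monotone-likelihood
#' (separation) warnings from the fitter are surfaced with a diagnostic.
#'
#' @param data data.frame holding the survival record and covariates.
#' @param covariates covariate column names.
#' @param time,event column names of the follow-up time (> 0, years) and
#'   0/1 event indicator.
#' @param ties tie-handling method (default `"efron"`).
#' @return data.frame, one row per covariate: term, log_hr, se, hr, ci_low,
#'   ci_high (HR scale), z, p, n, n_events; attribute `"fit"` holds the
#'   underlying `coxph` object.
#' @export
fitCox <- function(data, covariates, time = "time", event = "event",
                   ties = "efron") {
  data <- as.data.frame(data)
  stopifnot(all(c(time, event, covariates) %in% names(data)))
  if (any(data[[time]] <= 0)) stop("follow-up times must be positive")
  if (sum(data[[event]]) < 1) stop("need at least one event")
  form <- as.formula(paste0(
    "survival::Surv(`", time, "`, `", event, "`) ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(form, data = data, ties = ties),
    warning = function(w) {
      if (grepl("coefficient may be infinite|Loglik converged",
                conditionMessage(w))) {
        warning("possible monotone likelihood (separation): ",
                conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm),
                    log_hr = sm[, "coef"],
                    se = sm[, "se(coef)"],
                    hr = exp(sm[, "coef"]),
                    ci_low = exp(sm[, "coef"] - Z95 * sm[, "se(coef)"]),
                    ci_high = exp(sm[, "coef"] + Z95 * sm[, "se(coef)"]),
                    z = sm[, "z"],
                    p = sm[, "Pr(>|z|)"],
                    n = fit$n, n_events = fit$nevent,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Per-protein Cox associations with incident events
#'
#' One Cox fit per protein (z-scored on the analysis sample), adjusted for
#' the covariate set, after removing individuals with prevalent disease at
#' baseline (when flagged) and proteins failing the below-detection-limit
#' rule.  Unadjusted p-values are reported; per-protein model failures are
#' logged and skipped so one degenerate trait cannot abort the panel.
#'
#' @param panel numeric matrix, individuals x proteins.
#' @param data data.frame with the survival record, covariates and (when
#'   `exclude_prevalent`) a `prevalent_cvd` flag, rows aligned to `panel`.
#' @param adjustment an [adjustmentSet()] or NULL.
#' @param lod_flags optional logical matrix matching `panel`; proteins
#'   exceeding `max_below_frac` below-LOD are excluded.
#' @param exclude_prevalent drop rows with `prevalent_cvd == 1`.
#' @param max_below_frac below-LOD exclusion threshold.
#' @param time,event survival column names.
#' @return data.frame of `HazardResult` rows (trait, log_hr, se, hr, ci,
#'   p, n, n_events, adjustment_set); attribute `"failures"` logs skipped
#'   proteins, `"excluded_lod"` the detection-limit exclusions.
#' @export
proteinCvdAssoc <- function(panel, data, adjustment = NULL, lod_flags = NULL,
                            exclude_prevalent = TRUE, max_below_frac = 0.99,
                            time = "time_years", event = "event") {
  data <- as.data.frame(data)
  stopifnot(nrow(panel) == nrow(data))
  excluded_lod <- character()
  if (!is.null(lod_flags)) {
    panel <- excludeLowDetect(panel, lod_flags, max_below_frac)
    excluded_lod <- attr(panel, "excluded")
  }
  if (exclude_prevalent && "prevalent_cvd" %in% names(data)) {
    keep <- data$prevalent_cvd == 0
    panel <- panel[keep, , drop = FALSE]
    data <- data[keep, , drop = FALSE]
  }
  covs <- if (is.null(adjustment)) character() else adjustment$covariates
  label <- if (is.null(adjustment)) "unadjusted" else adjustment$label
  res <- vector("list", ncol(panel))
  fails <- character()
  for (j in seq_len(ncol(panel))) {
    trait <- colnames(panel)[j]
    res[[j]] <- tryCatch({
      dat <- cbind(.prot = standardize(panel[, j]), data)
      fit <- fitCox(dat, c(".prot", covs), time = time, event = event)
      row <- fit[fit$term == "`.prot`" | fit$term == ".prot", ][1, ]
      data.frame(trait = trait, log_hr = row$log_hr, se = row$se,
                 hr = row$hr, ci_low = row$ci_low, ci_high = row$ci_high,
                 p = row$p, n = row$n, n_events = row$n_events,
                 adjustment_set = label, stringsAsFactors = FALSE)
    }, error = function(e) {
      fails <<- c(fails, sprintf("%s: %s", trait, conditionMessage(e)))
      NULL
    })
  }
  out <- do.call(rbind, res)
  attr(out, "failures") <- fails
  attr(out, "excluded_lod") <- excluded_lod
  out
}

## plain percent-attenuation arithmetic, exposed for identity checks
#' @rdname attenuation
#' @param base_log_hr,adjusted_log_hr exposure log hazard ratios before and
#'   after mediator adjustment.
#' @export
attenuationPercent <- function(base_log_hr, adjusted_log_hr) {
  if (base_log_hr == 0) stop("percent attenuation undefined at base 0")
  100 * (base_log_hr - adjusted_log_hr) / base_log_hr
}

#' Attenuation-based mediation of an exposure-event association
#'
#' Fits the Cox model twice — with the base covariates, then additionally
#' with the putative mediators — and reports the percent attenuation of the
#' exposure log hazard ratio, `100 * (base - adjusted) / base`.  A positive
#' percentage means the mediators move the exposure association toward the
#' null.  When the base association is indistinguishable from zero
#' (|z| < 0.1) only the absolute change is returned, since a percentage of
#' a null effect is not interpretable.  The `"hr"` scale instead attenuates
#' the excess hazard, `100 * (HR_base - HR_adj) / (HR_base - 1)`.
#'
#' @param data data.frame with survival record, exposure, covariates and
#'   mediators.
#' @param exposure exposure column name (must not be in the mediators).
#' @param base_covariates covariate names of the base model (exposure is
#'   added automatically).
#' @param mediators mediator column names, disjoint from the base set.
#' @param scale `"loghr"` (primary) or `"hr"`.
#' @param time,event survival column names.
#' @param mediator_set label for the result row.
#' @return one-row data.frame (`AttenuationResult`): base_log_hr,
#'   adjusted_log_hr, absolute_change, percent_attenuation, scale,
#'   mediator_set.
#' @export
attenuation <- function(data, exposure, base_covariates, mediators,
                        scale = c("loghr", "hr"), time = "time_years",
                        event = "event", mediator_set = NULL) {
  scale <- match.arg(scale)
  if (exposure %in% mediators || length(intersect(base_covariates, mediators)))
    stop("mediators must be disjoint from the exposure and base covariates")
  base <- fitCox(data, c(exposure, base_covariates), time = time,
                 event = event)
  adj <- fitCox(data, c(exposure, base_covariates, mediators), time = time,
                event = event)
  pick <- function(fit) fit[fit$term %in% c(exposure, sprintf("`%s`", exposure)), ][1, ]
  b <- pick(base)
  a <- pick(adj)
  pct <- NA_real_
  if (abs(b$z) < 0.1) {
    warning("base exposure association indistinguishable from 0; ",
            "returning absolute change only")
  } else if (scale == "loghr") {
    pct <- attenuationPercent(b$log_hr, a$log_hr)
  } else {
    pct <- 100 * (b$hr - a$hr) / (b$hr - 1)
  }
  data.frame(base_log_hr = b$log_hr, adjusted_log_hr = a$log_hr,
             absolute_change = b$log_hr - a$log_hr,
             percent_attenuation = pct, scale = scale,
             mediator_set = mediator_set %||% paste(mediators, collapse = "+"),
             stringsAsFactors = FALSE)
}
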