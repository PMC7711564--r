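## Internal helpers shared across modules.

# 97.5% normal quantile used for all 95% intervals.
Z95 <- qnorm(0.975)

#' Derive a deterministic substream seed
#'
#' All randomness in a run flows from one master seed; per-stage seeds are
#' derived by hashing the stage label so that stages can be rerun in any
#' order without changing their draws.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer in [0, 2^31 - 1).
#' @keywords internal
seedFor <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) %% 1000003L) * 2099L + (h %% 1000003L)) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## logsumexp / log(exp(a) - exp(b)) with a >= b, stable in the tails
logsum <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

logdiff <- function(a, b) {
  stopifnot(a >= b)
  a + log1p(-exp(b - a))
}

## Wald-style two-sided p from estimate and SE
waldP <- function(est, se) 2 * pnorm(-abs(est / se))

## assemble a one-row MR result table; extras appended as columns
mrResultRow <- function(method, estimate, se, n_variants, ...) {
  out <- data.frame(
    method = method,
    estimate = estimate,
    se = se,
    ci_low = estimate - Z95 * se,
    ci_high = estimate + Z95 * se,
    p = waldP(estimate, se),
    n_variants = n_variants,
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}
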