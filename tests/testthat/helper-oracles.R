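## Independent oracles and shared fixtures, built in code.

## Efron partial log-likelihood by direct enumeration (single covariate).
## Deliberately naive: loops over event times so it can serve as an
## independent check of the package's Cox fitting route.
coxPartialLogLik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

## brute-force maximization on an interval
oracleCoxFit <- function(time, event, x) {
  optimize(function(b) -coxPartialLogLik(b, time, event, x),
           interval = c(-8, 8), tol = 1e-9)$minimum
}

## small cached synthetic study shared across test files
fixtureStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- makeStudy(simConfigDefault(nGwas = 3000L, nSubcohort = 400L,
                                           nVariants = 40L, seed = 42L))
    }
    cache
  }
})

## per-variant summary-statistic generator for the two-sample estimators:
## gamma_j are true variant-exposure effects, `pleiotropy` direct outcome
## effects (invalid instruments), `effect` the true causal slope
simSummaryAssocs <- function(k, effect, se_exp = 0.005, se_out = 0.01,
                             pleiotropy = rep(0, k), seed = 1L) {
  set.seed(seed)
  gamma <- runif(k, 0.05, 0.15)
  data.frame(
    beta_exposure = rnorm(k, gamma, se_exp),
    se_exposure = se_exp,
    beta_outcome = rnorm(k, effect * gamma + pleiotropy, se_out),
    se_outcome = se_out)
}

## one rep of the confounded split-sample design: a polygenic score
## explaining ~2% of exposure variance, a confounder that inflates the
## observational estimate, and a protein with known causal effect
simTslsRep <- function(n1, n2, m = 20L, beta_true = 0.35,
                       gamma_prot = 0.5, conf_exp = 0.45,
                       target_r2 = 0.02, seed = 1L) {
  g <- simulateGenotypes(n1, rep(0.3, m), seed = seed)
  set.seed(seed + 1L)
  u <- rnorm(n1)
  x <- simulateExposure(g, rep(1, m), target_r2, confounder = u,
                        confounder_effect = conf_exp, seed = seed + 2L)
  xz <- attr(x, "exposure_z")
  score <- attr(x, "score")
  set.seed(seed + 3L)
  idx <- sample.int(n1, n2)
  resid_sd <- sqrt(1 - beta_true^2 - gamma_prot^2)
  prot <- beta_true * xz[idx] + gamma_prot * u[idx] +
    resid_sd * rnorm(n2)
  list(d1 = data.frame(score = score, exposure = xz),
       d2 = data.frame(score = score[idx], outcome = prot,
                       exposure = xz[idx]))
}
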