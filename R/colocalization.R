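#' Approximate-Bayes-factor colocalization of two traits at a locus
#'
#' Single-causal-variant colocalization from per-variant summary statistics.
#' Each variant's association with each trait is summarized by a Wakefield
#' approximate Bayes factor
#' \deqn{ABF = \sqrt{V/(V+W)}\,\exp\{z^2 W / (2 (V+W))\},}
#' with `V = se^2` and prior effect variance `W` (default `0.15^2` for a
#' quantitative trait, `0.2^2` on the log-odds scale for a binary trait).
#' Variant-level ABFs are combined into the five locus hypotheses —
#' no association (H0), trait-1 only (H1), trait-2 only (H2), two distinct
#' causal variants (H3), one shared causal variant (H4) — under per-variant
#' priors `p1`, `p2`, `p12`, and posterior probabilities PP0-PP4 are
#' returned (they sum to 1).
#'
#' @param stats1,stats2 data.frames with columns `id`, `beta`, `se`; the
#'   variant lists are intersected and aligned by id.
#' @param p1,p2 prior probability a variant is causal for trait 1 / 2 only.
#' @param p12 prior probability a variant is causal for both.
#' @param type1,type2 `"quant"` or `"cc"` (case-control), setting the
#'   default prior variance per trait.
#' @param W1,W2 optional explicit prior effect variances.
#' @return one-row `ColocResult` data.frame: pp0..pp4, n_variants, priors.
#' @examples
#' s1 <- data.frame(id = paste0("v", 1:50), beta = rnorm(50, 0, 0.02),
#'                  se = 0.02)
#' s2 <- data.frame(id = paste0("v", 1:50), beta = rnorm(50, 0, 0.02),
#'                  se = 0.02)
#' colocAbf(s1, s2)
#' @export
colocAbf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     type1 = c("quant", "cc"), type2 = c("quant", "cc"),
                     W1 = NULL, W2 = NULL) {
  type1 <- match.arg(type1)
  type2 <- match.arg(type2)
  ids <- intersect(stats1$id, stats2$id)
  if (length(ids) == 0L) stop("no shared variants between the two traits")
  s1 <- stats1[match(ids, stats1$id), ]
  s2 <- stats2[match(ids, stats2$id), ]
  W1 <- W1 %||% if (type1 == "quant") 0.15^2 else 0.2^2
  W2 <- W2 %||% if (type2 == "quant") 0.15^2 else 0.2^2
  labf <- function(beta, se, W) {
    V <- se^2
    r <- W / (V + W)
    0.5 * log(1 - r) + (beta / se)^2 * r / 2
  }
  l1 <- labf(s1$beta, s1$se, W1)
  l2 <- labf(s2$beta, s2$se, W2)
  s_l1 <- logsum(l1)
  s_l2 <- logsum(l2)
  s_l12 <- logsum(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(p1) + s_l1,
          h2 = log(p2) + s_l2,
          h3 = log(p1) + log(p2) + logdiff(s_l1 + s_l2, s_l12),
          h4 = log(p12) + s_l12)
  pp <- exp(lh - logsum(lh))
  data.frame(pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
             pp3 = pp[["h3"]], pp4 = pp[["h4"]],
             n_variants = length(ids), p1 = p1, p2 = p2, p12 = p12)
}
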