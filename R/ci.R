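# Confidence-interval machinery for the accuracy statistics. Proportions
# are handled on the [0, 1] scale here; callers rescale to percent.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail probabilities via beta quantiles. Guaranteed
#' coverage at or above the nominal level for every true proportion.
#'
#' @param k number of successes (non-negative integer).
#' @param n number of trials (positive integer, `k <= n`).
#' @param conf_level confidence level, default 0.95.
#' @return numeric vector `c(lower, upper)` on the [0, 1] scale.
#' @examples
#' clopper_pearson(39, 40)   # c(0.868, 0.999) to 3 dp
#' @export
clopper_pearson <- function(k, n, conf_level = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, n >= 1, k <= n,
            conf_level > 0, conf_level < 1)
  alpha <- 1 - conf_level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower, upper)
}

# Wilson score interval with continuity correction (Newcombe method 4).
# Used as the boundary fallback for predictive values where the logit
# interval is undefined (estimate exactly 0 or 1).
ci_wilson_cc <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  lower <- if (k == 0) 0 else {
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
      (2 * (n + z^2))
  }
  upper <- if (k == n) 1 else {
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
      (2 * (n + z^2))
  }
  c(max(0, lower), min(1, upper))
}

# Standard logit interval for predictive values (Mercaldo et al. 2007):
# the variance of logit(PPV)/logit(NPV) is assembled from the grouped
# binomial variances of sensitivity (n1 diseased) and specificity (n0
# non-diseased), not from the naive k/n variance of the predictive value
# itself. Falls back to Wilson-cc at boundary estimates.
ci_logit_pv <- function(pv, sens, spec, n1, n0, which = c("ppv", "npv"),
                        conf_level = 0.95) {
  which <- match.arg(which)
  if (pv <= 0 || pv >= 1) {
    stop("ci_logit_pv is undefined at a boundary estimate", call. = FALSE)
  }
  v <- if (which == "ppv") {
    (1 - sens) / sens / n1 + spec / (1 - spec) / n0
  } else {
    sens / (1 - sens) / n1 + (1 - spec) / spec / n0
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  theta <- stats::qlogis(pv)
  stats::plogis(theta + c(-1, 1) * z * sqrt(v))
}

# Log-method interval for a likelihood ratio (Altman): CI on the log scale
# with SE assembled from the two binomial components.
ci_log_lr <- function(lr, se_log, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lr * exp(c(-1, 1) * z * se_log)
}

# Hanley-McNeil standard error for an AUC estimated from n1 positives and
# n0 negatives; Wald CI truncated to [0, 1].
ci_hanley_mcneil <- function(auc, n1, n0, conf_level = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- auc + c(-1, 1) * z * sqrt(max(v, 0))
  c(max(0, ci[1]), min(1, ci[2]))
}
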