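# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package internals.

# Flat chain of explicit comparisons over the published criteria, one
# record at a time (the engine is checked against this on random input).
ref_classify_one <- function(fvc_pct, fev1_pct, ratio) {
  if (ratio < 0.7 && fvc_pct >= 80) return("obstructive")
  if (ratio < 0.7 && fvc_pct < 80) return("mixed")
  if (ratio >= 0.7 && fvc_pct < 80) return("spirometric_restriction")
  "normal"
}

ref_grade_one <- function(pattern, fvc_pct, fev1_pct) {
  if (pattern == "normal") return("not_applicable")
  x <- if (pattern == "spirometric_restriction") fvc_pct else fev1_pct
  if (x >= 70) "mild"
  else if (x >= 60) "moderate"
  else if (x >= 50) "moderately_severe"
  else if (x >= 35) "severe"
  else "very_severe"
}

# Cohen's kappa computed straight from the definition on raw label lists:
# observed agreement and marginal-product chance agreement by counting.
ref_kappa_from_labels <- function(a, b, categories) {
  po <- mean(a == b)
  pe <- 0
  for (cat in categories) pe <- pe + mean(a == cat) * mean(b == cat)
  (po - pe) / (1 - pe)
}

# Clopper-Pearson endpoints by numerically inverting the binomial tail
# probabilities (no beta quantiles involved).
ref_clopper_pearson <- function(k, n, alpha = 0.05) {
  lower <- if (k == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }
  upper <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }
  c(lower, upper)
}

pattern_levels <- c("normal", "obstructive", "spirometric_restriction",
                    "mixed")

# The study's printed dichotomous counts as confusion tables.
table1_confusions <- function() {
  list(
    pulm1 = confusion_2x2(tp = 39, fp = 4, fn = 1, tn = 74),
    pulm2 = confusion_2x2(tp = 42, fp = 1, fn = 0, tn = 75)
  )
}

get_stat <- function(acc, stat, col = "estimate") {
  acc[acc$statistic == stat, col]
}
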