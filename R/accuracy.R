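#' Dichotomize pattern labels into normal vs impaired
#'
#' For diagnostic-accuracy work the four-level pattern call is collapsed to
#' a binary one: obstructive, spirometric restriction and mixed patterns
#' are "impaired" (the positive class), normal stays "normal".
#'
#' @param pattern character or factor vector of pattern labels.
#' @return factor with levels `normal`, `impaired`.
#' @examples
#' dichotomize_pattern(c("normal", "mixed", "obstructive"))
#' @export
dichotomize_pattern <- function(pattern) {
  pattern <- as.character(pattern)
  bad <- setdiff(unique(pattern[!is.na(pattern)]), PATTERN_LEVELS)
  if (length(bad)) {
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(ifelse(is.na(pattern), NA,
                ifelse(pattern == "normal", "normal", "impaired")),
         levels = DICHOTOMY_LEVELS)
}

#' Build or construct a 2x2 confusion table
#'
#' `confusion_2x2()` constructs the table from counts; `build_confusion()`
#' cross-tabulates paired test and gold-standard labels. The positive class
#' is "impaired": TP counts cases both raters call impaired, TN cases both
#' call normal.
#'
#' @param tp,fp,fn,tn non-negative integer counts (true positive, false
#'   positive, false negative, true negative).
#' @return an object of class `confusion_2x2`.
#' @examples
#' confusion_2x2(tp = 39, fp = 4, fn = 1, tn = 74)
#' @export
confusion_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(!is.na(counts)), all(counts >= 0),
            all(counts == round(counts)))
  if (sum(counts) == 0) stop("empty confusion table", call. = FALSE)
  structure(as.list(counts), n = sum(counts), class = "confusion_2x2")
}

#' @rdname confusion_2x2
#' @param test,gold equal-length vectors of `normal`/`impaired` labels
#'   (missing calls are dropped pairwise).
#' @export
build_confusion <- function(test, gold) {
  if (length(test) != length(gold)) {
    stop("`test` and `gold` must have the same length", call. = FALSE)
  }
  test <- as.character(test); gold <- as.character(gold)
  keep <- !is.na(test) & !is.na(gold)
  test <- test[keep]; gold <- gold[keep]
  if (!length(test)) stop("no complete label pairs", call. = FALSE)
  bad <- setdiff(unique(c(test, gold)), DICHOTOMY_LEVELS)
  if (length(bad)) {
    stop("labels must be \"normal\" or \"impaired\"; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  confusion_2x2(
    tp = sum(test == "impaired" & gold == "impaired"),
    fp = sum(test == "impaired" & gold == "normal"),
    fn = sum(test == "normal" & gold == "impaired"),
    tn = sum(test == "normal" & gold == "normal")
  )
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(test = c("normal", "impaired"),
                              gold = c("normal", "impaired")))
  cat(sprintf("2x2 confusion table (n = %d, positive = impaired)\n",
              attr(x, "n")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.confusion_2x2 <- function(x, ...) {
  matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
         dimnames = list(test = c("normal", "impaired"),
                         gold = c("normal", "impaired")))
}

# One accuracy-statistic row with its interval and method tag.
accuracy_row <- function(statistic, estimate, ci, method) {
  data.frame(statistic = statistic, estimate = estimate,
             ci_low = ci[1], ci_high = ci[2], ci_method = method,
             stringsAsFactors = FALSE)
}

#' Diagnostic accuracy of a binary classifier against a gold standard
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values, likelihood ratios, overall accuracy and the single-threshold
#' AUC from a 2x2 confusion table, each with a 95% (by default) confidence
#' interval. Interval methods follow common diagnostic-calculator practice
#' and are recorded per row: exact Clopper-Pearson for sensitivity,
#' specificity and accuracy; the Mercaldo standard logit interval for the
#' predictive values (Wilson continuity-corrected at a boundary estimate,
#' where the logit interval is undefined); the log method for likelihood
#' ratios; Hanley-McNeil for the AUC.
#'
#' Proportions are reported as percentages, likelihood ratios as ratios,
#' and the AUC on the [0, 1] scale.
#'
#' @param x a [confusion_2x2] object.
#' @param conf_level confidence level, default 0.95.
#' @return object of class `diag_accuracy`: a data.frame with columns
#'   `statistic`, `estimate`, `ci_low`, `ci_high`, `ci_method`.
#' @examples
#' diag_accuracy(confusion_2x2(tp = 39, fp = 4, fn = 1, tn = 74))
#' @export
diag_accuracy <- function(x, conf_level = 0.95) {
  stopifnot(inherits(x, "confusion_2x2"))
  tp <- x$tp; fp <- x$fp; fn <- x$fn; tn <- x$tn
  n1 <- tp + fn  # gold impaired
  n0 <- tn + fp  # gold normal
  n <- n1 + n0
  if (n1 == 0 || n0 == 0) {
    stop("both gold-standard classes must be represented", call. = FALSE)
  }

  sens <- tp / n1
  spec <- tn / n0
  acc <- (tp + tn) / n

  rows <- rbind(
    accuracy_row("sensitivity", 100 * sens,
                 100 * clopper_pearson(tp, n1, conf_level), "clopper_pearson"),
    accuracy_row("specificity", 100 * spec,
                 100 * clopper_pearson(tn, n0, conf_level), "clopper_pearson"),
    pv_row("ppv", tp, tp + fp, sens, spec, n1, n0, conf_level),
    pv_row("npv", tn, tn + fn, sens, spec, n1, n0, conf_level),
    lr_rows(tp, fp, fn, tn, conf_level),
    accuracy_row("accuracy", 100 * acc,
                 100 * clopper_pearson(tp + tn, n, conf_level),
                 "clopper_pearson"),
    accuracy_row("auc", (sens + spec) / 2,
                 ci_hanley_mcneil((sens + spec) / 2, n1, n0, conf_level),
                 "hanley_mcneil")
  )
  structure(rows, class = c("diag_accuracy", "data.frame"),
            confusion = x, conf_level = conf_level)
}

pv_row <- function(which, k, denom, sens, spec, n1, n0, conf_level) {
  if (denom == 0) {
    stop(sprintf("%s undefined: empty test-%s margin", toupper(which),
                 if (which == "ppv") "positive" else "negative"),
         call. = FALSE)
  }
  pv <- k / denom
  # the grouped logit variance needs its two binomial components finite
  v_ok <- if (which == "ppv") sens > 0 && spec < 1 else sens < 1 && spec > 0
  if (pv > 0 && pv < 1 && v_ok) {
    ci <- ci_logit_pv(pv, sens, spec, n1, n0, which, conf_level)
    accuracy_row(which, 100 * pv, 100 * ci, "mercaldo_logit")
  } else {
    accuracy_row(which, 100 * pv, 100 * ci_wilson_cc(k, denom, conf_level),
                 "wilson_cc")
  }
}

lr_rows <- function(tp, fp, fn, tn, conf_level) {
  n1 <- tp + fn; n0 <- tn + fp
  sens <- tp / n1; spec <- tn / n0

  # +LR = sens / (1 - spec); infinite at spec = 1 with an open upper CI
  if (spec == 1) {
    plr <- accuracy_row("plr", Inf, c(NA_real_, Inf), "log")
  } else {
    plr_est <- sens / (1 - spec)
    if (tp == 0) {
      plr <- accuracy_row("plr", 0, c(NA_real_, NA_real_), "log")
    } else {
      se_log <- sqrt(1 / tp - 1 / n1 + 1 / fp - 1 / n0)
      plr <- accuracy_row("plr", plr_est,
                          ci_log_lr(plr_est, se_log, conf_level), "log")
    }
  }

  # -LR = (1 - sens) / spec
  if (spec == 0) {
    nlr <- accuracy_row("nlr", NaN, c(NA_real_, NA_real_), "log")
  } else {
    nlr_est <- (1 - sens) / spec
    if (fn == 0) {
      # a perfect -LR of 0 has no log-scale interval
      nlr <- accuracy_row("nlr", 0, c(NA_real_, NA_real_), "log")
    } else {
      se_log <- sqrt(1 / fn - 1 / n1 + 1 / tn - 1 / n0)
      nlr <- accuracy_row("nlr", nlr_est,
                          ci_log_lr(nlr_est, se_log, conf_level), "log")
    }
  }
  rbind(plr, nlr)
}

#' @export
print.diag_accuracy <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy (n = %d, %.0f%% CI)\n",
              attr(attr(x, "confusion"), "n"), 100 * attr(x, "conf_level")))
  fmt <- function(est, lo, hi, pct, dp) {
    fmt1 <- function(v) {
      if (is.na(v)) return("NA")
      if (is.infinite(v)) return("Inf")
      out <- sprintf(paste0("%.", dp, "f"), v)
      # a non-degenerate endpoint is reported strictly inside the range
      if (pct && out == "100.0" && v < 100) out <- "99.9"
      if (pct && out == "0.0" && v > 0) out <- "0.1"
      out
    }
    if (is.na(lo) && is.na(hi)) fmt1(est)
    else sprintf("%s (%s-%s)", fmt1(est), fmt1(lo), fmt1(hi))
  }
  labels <- c(sensitivity = "Sensitivity, %", specificity = "Specificity, %",
              ppv = "PPV, %", npv = "NPV, %", plr = "+LR", nlr = "-LR",
              accuracy = "Accuracy, %", auc = "AUC")
  for (i in seq_len(nrow(x))) {
    st <- x$statistic[i]
    pct <- st %in% c("sensitivity", "specificity", "ppv", "npv", "accuracy")
    dp <- if (pct) 1 else if (st == "auc") 3 else 2
    cat(sprintf("  %-16s %s\n", labels[[st]],
                fmt(x$estimate[i], x$ci_low[i], x$ci_high[i], pct, dp)))
  }
  invisible(x)
}

# Single-statistic accessors ------------------------------------------------

one_stat <- function(x, stat, conf_level) {
  res <- diag_accuracy(x, conf_level)
  res[res$statistic == stat, , drop = FALSE]
}

#' Individual accuracy statistics
#'
#' Convenience accessors returning one row of [diag_accuracy()].
#' `sensitivity()` and `specificity()` carry exact Clopper-Pearson
#' intervals, `ppv()`/`npv()` Mercaldo logit intervals, and
#' `overall_accuracy()` a Clopper-Pearson interval; all as percentages.
#'
#' @inheritParams diag_accuracy
#' @return one-row data.frame with `statistic`, `estimate`, `ci_low`,
#'   `ci_high`, `ci_method`.
#' @examples
#' sensitivity(confusion_2x2(tp = 39, fp = 4, fn = 1, tn = 74))
#' @export
sensitivity <- function(x, conf_level = 0.95) one_stat(x, "sensitivity", conf_level)

#' @rdname sensitivity
#' @export
specificity <- function(x, conf_level = 0.95) one_stat(x, "specificity", conf_level)

#' @rdname sensitivity
#' @export
ppv <- function(x, conf_level = 0.95) one_stat(x, "ppv", conf_level)

#' @rdname sensitivity
#' @export
npv <- function(x, conf_level = 0.95) one_stat(x, "npv", conf_level)

#' @rdname sensitivity
#' @export
overall_accuracy <- function(x, conf_level = 0.95) one_stat(x, "accuracy", conf_level)

#' Likelihood ratios of a binary test
#'
#' The positive likelihood ratio sens/(1-spec) and negative likelihood
#' ratio (1-sens)/spec with log-method confidence intervals. A perfect
#' specificity yields an infinite +LR with an open upper interval; a
#' perfect sensitivity yields a -LR of exactly 0 (no log-scale interval).
#'
#' @inheritParams diag_accuracy
#' @return two-row data.frame (`plr`, `nlr`).
#' @examples
#' likelihood_ratios(confusion_2x2(tp = 39, fp = 4, fn = 1, tn = 74))
#' @export
likelihood_ratios <- function(x, conf_level = 0.95) {
  res <- diag_accuracy(x, conf_level)
  res[res$statistic %in% c("plr", "nlr"), , drop = FALSE]
}

#' Single-threshold ROC area under the curve
#'
#' For a binary (single-threshold) classifier the empirical ROC curve has
#' one interior vertex at (1-spec, sens); its trapezoidal area reduces to
#' (sens+spec)/2. The confidence interval uses the Hanley-McNeil standard
#' error.
#'
#' @inheritParams diag_accuracy
#' @return one-row data.frame with the AUC on the [0, 1] scale.
#' @export
binary_auc <- function(x, conf_level = 0.95) one_stat(x, "auc", conf_level)

#' Sample size for estimating a proportion to a given precision
#'
#' The standard Wald planning formula: the smallest n such that
#' z^2 p (1-p) / d^2 <= n, where d is the desired half-width of the
#' confidence interval for an anticipated proportion p.
#'
#' @param p anticipated proportion, in (0, 1).
#' @param d desired half-width of the interval, same scale, > 0.
#' @param conf_level confidence level, default 0.95.
#' @return integer sample size.
#' @examples
#' required_sample_size(0.9, 0.07)  # 71
#' @export
required_sample_size <- function(p, d, conf_level = 0.95) {
  stopifnot(p > 0, p < 1, d > 0, conf_level > 0, conf_level < 1)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / d^2))
}
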