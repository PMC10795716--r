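#' Specification of a synthetic spirometry cohort
#'
#' Describes the statistical structure of a cohort to generate: size,
#' pattern prevalence, severity mix within impaired patterns, the rate of
#' positive bronchodilator responses, and a guard margin keeping every
#' generated index away from the decision thresholds so that the intended
#' label is recovered exactly on interpretation.
#'
#' Defaults mirror the validation-study conditions: 118 subjects, about
#' 64% normal and at least 10% of each impaired pattern.
#'
#' @param n cohort size (non-negative integer).
#' @param pattern_prevalence named probability vector over the four
#'   patterns; must sum to 1.
#' @param severity_mix named probability vector over the five severity
#'   grades used within impaired patterns; must sum to 1.
#' @param bd_positive_rate probability of a positive bronchodilator
#'   response, in [0, 1].
#' @param boundary_margin minimum distance, in percent-of-predicted
#'   points, of generated indices from every decision threshold (the
#'   ratio margin is `boundary_margin / 100`). Must leave every severity
#'   band non-empty (< 5).
#' @param seed optional RNG seed for reproducible generation.
#' @return an object of class `cohort_spec`.
#' @examples
#' cohort_spec(n = 118)
#' @export
cohort_spec <- function(n = 118,
                        pattern_prevalence = c(normal = 0.64,
                                               obstructive = 0.12,
                                               spirometric_restriction = 0.14,
                                               mixed = 0.10),
                        severity_mix = c(mild = 0.40, moderate = 0.25,
                                         moderately_severe = 0.15,
                                         severe = 0.12, very_severe = 0.08),
                        bd_positive_rate = 0.15,
                        boundary_margin = 1,
                        seed = NULL) {
  stopifnot(length(n) == 1L, n >= 0, n == round(n))
  if (!setequal(names(pattern_prevalence), PATTERN_LEVELS)) {
    stop("`pattern_prevalence` must name exactly the four patterns",
         call. = FALSE)
  }
  if (!setequal(names(severity_mix), setdiff(SEVERITY_LEVELS, "not_applicable"))) {
    stop("`severity_mix` must name exactly the five severity grades",
         call. = FALSE)
  }
  stopifnot(all(pattern_prevalence >= 0), all(severity_mix >= 0),
            abs(sum(pattern_prevalence) - 1) < 1e-8,
            abs(sum(severity_mix) - 1) < 1e-8,
            bd_positive_rate >= 0, bd_positive_rate <= 1,
            boundary_margin >= 0)
  if (boundary_margin >= 5) {
    stop("`boundary_margin` >= 5 leaves severity bands empty; generation infeasible",
         call. = FALSE)
  }
  structure(
    list(n = as.integer(n),
         pattern_prevalence = pattern_prevalence[PATTERN_LEVELS],
         severity_mix = severity_mix[setdiff(SEVERITY_LEVELS, "not_applicable")],
         bd_positive_rate = bd_positive_rate,
         boundary_margin = boundary_margin,
         seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic spirometry cohort
#'
#' Samples, per subject, a target pattern from the prevalence vector, then
#' draws the three interpretation indices uniformly inside the target
#' pattern's decision region shrunk by the boundary margin (severity bands
#' are respected for impaired patterns, so target severity is recovered
#' too). Absolute litre volumes are back-computed from the indices and a
#' predicted FVC drawn uniformly from a broad physiological range;
#' realism of the predicted values themselves is not a goal. Ground-truth
#' columns (`true_pattern`, `true_severity`, `true_bd`) are carried for
#' round-trip testing and ignored by [interpret()].
#'
#' @param spec a [cohort_spec()].
#' @return a [spiro_records] object with `spec$n` rows and ground-truth
#'   columns appended.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 50, seed = 1))
#' table(interpret(cohort)$pattern) # matches table(cohort$true_pattern)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  if (n == 0L) {
    empty <- data.frame(subject_id = character(), sex = character(),
                        age = numeric(), height = numeric(), weight = numeric(),
                        fvc_pre_L = numeric(), fev1_pre_L = numeric(),
                        fvc_post_L = numeric(), fev1_post_L = numeric(),
                        fvc_pred_L = numeric(), fev1_pred_L = numeric(),
                        true_pattern = character(), true_severity = character(),
                        true_bd = character(), stringsAsFactors = FALSE)
    return(spiro_records(empty))
  }
  m <- spec$boundary_margin
  mr <- m / 100

  pattern <- sample(PATTERN_LEVELS, n, replace = TRUE,
                    prob = spec$pattern_prevalence)
  severity <- ifelse(pattern == "normal", "not_applicable",
                     sample(names(spec$severity_mix), n, replace = TRUE,
                            prob = spec$severity_mix))

  runif_in <- function(k, lo, hi) {
    if (any(hi <= lo)) {
      stop("boundary margin too large: empty generation region", call. = FALSE)
    }
    stats::runif(k, lo, hi)
  }

  # severity band for the graded index, shrunk by the margin; `cap` bounds
  # the band from above when the pattern itself requires a reduced index
  severity_band <- function(grade, cap) {
    lo <- c(mild = 70, moderate = 60, moderately_severe = 50,
            severe = 35, very_severe = 15)[grade]
    hi <- c(mild = cap, moderate = 70, moderately_severe = 60,
            severe = 50, very_severe = 35)[grade]
    lo <- ifelse(grade == "very_severe", lo, lo + m)
    hi <- ifelse(grade == "mild" & cap > 100, hi, hi - m)
    c(lo, hi)
  }

  fvc_pct <- fev1_pct <- ratio <- numeric(n)
  for (i in seq_len(n)) {
    p <- pattern[i]
    if (p == "normal") {
      fvc_pct[i] <- runif_in(1, 80 + m, 130)
      fev1_pct[i] <- runif_in(1, 80 + m, 130)
      ratio[i] <- runif_in(1, 0.7 + mr, 0.92)
    } else if (p == "obstructive") {
      fvc_pct[i] <- runif_in(1, 80 + m, 130)
      b <- severity_band(severity[i], 120)
      fev1_pct[i] <- runif_in(1, b[1], b[2])
      ratio[i] <- runif_in(1, 0.4, 0.7 - mr)
    } else if (p == "spirometric_restriction") {
      b <- severity_band(severity[i], 80)
      fvc_pct[i] <- runif_in(1, b[1], b[2])
      fev1_pct[i] <- runif_in(1, 60, 115)
      ratio[i] <- runif_in(1, 0.7 + mr, 0.92)
    } else { # mixed: both FVC and the ratio reduced, FEV1 reduced too
      fvc_pct[i] <- runif_in(1, 45 + m, 80 - m)
      b <- severity_band(severity[i], 80)
      fev1_pct[i] <- runif_in(1, b[1], b[2])
      ratio[i] <- runif_in(1, 0.4, 0.7 - mr)
    }
  }

  # back-compute litres: predicted FVC drawn from a broad adult range, the
  # predicted FEV1 is whatever makes the three indices consistent
  fvc_pred <- stats::runif(n, 2.8, 5.8)
  fvc_pre <- fvc_pct / 100 * fvc_pred
  fev1_pre <- ratio * fvc_pre
  fev1_pred <- fev1_pre / (fev1_pct / 100)

  # bronchodilator response
  bd_class <- ifelse(stats::runif(n) < spec$bd_positive_rate, "positive",
                     ifelse(stats::runif(n) < 0.5, "not_significant",
                            "negative_unmodified"))
  d_pct <- numeric(n)
  fev1_post <- fev1_pre
  fvc_post <- fvc_pre
  pos <- bd_class == "positive"
  d_pct[pos] <- stats::runif(sum(pos), 15, 30)
  d_abs <- fev1_pre * d_pct / 100
  small <- pos & d_abs < 0.22
  d_abs[small] <- 0.22  # keep the absolute criterion clear of 0.2 L
  fev1_post[pos] <- fev1_pre[pos] + d_abs[pos]
  ns <- bd_class == "not_significant"
  fev1_post[ns] <- fev1_pre[ns] * (1 + stats::runif(sum(ns), 1, 8) / 100)
  neg <- bd_class == "negative_unmodified"
  fev1_post[neg] <- fev1_pre[neg] * (1 - stats::runif(sum(neg), 0, 4) / 100)
  fvc_post[neg] <- fvc_pre[neg] * (1 - stats::runif(sum(neg), 0, 4) / 100)
  fvc_post <- pmax(fvc_post, fev1_post * 1.02)  # post ratio stays physiological

  sex <- sample(c("male", "female"), n, replace = TRUE)
  cohort <- data.frame(
    subject_id = sprintf("SYN%04d", seq_len(n)),
    sex = sex,
    age = round(stats::runif(n, 35, 70)),
    height = round(stats::runif(n, 150, 190)),
    weight = round(stats::runif(n, 50, 100)),
    fvc_pre_L = fvc_pre, fev1_pre_L = fev1_pre,
    fvc_post_L = fvc_post, fev1_post_L = fev1_post,
    fvc_pred_L = fvc_pred, fev1_pred_L = fev1_pred,
    true_pattern = pattern, true_severity = severity, true_bd = bd_class,
    stringsAsFactors = FALSE
  )
  spiro_records(cohort)
}

#' Simulated rater behaviour
#'
#' `rater_model()` describes a rater by a row-stochastic confusion matrix
#' (true pattern in rows, called pattern in columns) and a probability of
#' omitting a call. `simulate_rater()` draws one call per true label from
#' the corresponding confusion row, replacing calls by NA at the omission
#' rate.
#'
#' @param confusion square row-stochastic matrix with identical row and
#'   column names (the category universe).
#' @param omission_rate probability a call is missing, in [0, 1).
#' @return `rater_model()`: an object of class `rater_model`.
#' @examples
#' ident <- diag(4)
#' dimnames(ident) <- list(levels <- c("normal", "obstructive",
#'                                     "spirometric_restriction", "mixed"),
#'                         levels)
#' m <- rater_model(ident)
#' simulate_rater(c("normal", "mixed"), m, seed = 1)
#' @export
rater_model <- function(confusion, omission_rate = 0) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) ||
      is.null(rownames(confusion)) ||
      !identical(rownames(confusion), colnames(confusion))) {
    stop("`confusion` must be square with identical row/column names",
         call. = FALSE)
  }
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-8)) {
    stop("`confusion` rows must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(omission_rate >= 0, omission_rate < 1)
  structure(list(confusion = confusion, omission_rate = omission_rate),
            class = "rater_model")
}

#' @rdname rater_model
#' @param truth character vector of true category labels.
#' @param model a `rater_model`.
#' @param seed optional RNG seed.
#' @return `simulate_rater()`: character vector of called labels with NA
#'   for omitted calls.
#' @export
simulate_rater <- function(truth, model, seed = NULL) {
  stopifnot(inherits(model, "rater_model"))
  if (!is.null(seed)) set.seed(seed)
  truth <- as.character(truth)
  cats <- rownames(model$confusion)
  bad <- setdiff(unique(truth), cats)
  if (length(bad)) {
    stop("truth label(s) outside the model's categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  calls <- vapply(truth, function(tr) {
    sample(cats, 1L, prob = model$confusion[tr, ])
  }, character(1), USE.NAMES = FALSE)
  if (model$omission_rate > 0) {
    calls[stats::runif(length(calls)) < model$omission_rate] <- NA_character_
  }
  calls
}

#' Expected kappa under a simulated rater model
#'
#' Closed-form expectation of Cohen's kappa for truth drawn from a
#' prevalence vector and calls drawn from the model's confusion rows:
#' po = sum_i p_i C_ii and pe = sum_i p_i q_i with q = p %*% C.
#'
#' @param prevalence probability vector over the categories (model row
#'   order).
#' @param model a [rater_model()].
#' @return the expected kappa (length-1 numeric).
#' @export
expected_kappa <- function(prevalence, model) {
  stopifnot(inherits(model, "rater_model"))
  C <- model$confusion
  stopifnot(length(prevalence) == nrow(C), abs(sum(prevalence) - 1) < 1e-8)
  po <- sum(prevalence * diag(C))
  q <- as.numeric(prevalence %*% C)
  pe <- sum(prevalence * q)
  (po - pe) / (1 - pe)
}
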