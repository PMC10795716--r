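#' Classify the spirometric pattern
#'
#' Maps the derived indices of each record onto the four conventional
#' patterns using the fixed-ratio criteria: a preserved FEV1/FVC ratio
#' (>= 0.70) with preserved FVC (>= 80% predicted) is normal; a reduced
#' ratio with preserved FVC is obstructive; a preserved ratio with reduced
#' FVC is spirometric restriction; reduced ratio and reduced FVC is mixed.
#'
#' The published criteria leave two cells of the (ratio, FVC%, FEV1%) space
#' uncovered, which this implementation resolves into a total partition:
#' \itemize{
#'   \item FVC% exactly at the threshold with a reduced ratio is classified
#'     obstructive ("not reduced" is >= 80 everywhere) and flagged
#'     \code{BOUNDARY_FVC_80}.
#'   \item Preserved ratio and FVC but FEV1% below 80 (the "non-specific"
#'     constellation) is classified normal and flagged
#'     \code{NONSPECIFIC_LOW_FEV1}.
#' }
#' A mixed pattern whose FEV1% is unexpectedly preserved (>= 80) is flagged
#' \code{MIXED_PRESERVED_FEV1}.
#'
#' @param indices data.frame with columns `fvc_pct`, `fev1_pct`, `ratio`
#'   (as produced by [derive_indices()]).
#' @param config a [spiro_config()] object with the thresholds.
#' @return data.frame with columns `pattern` (factor over the four
#'   patterns) and `flags` (character; `;`-separated warning codes, `""`
#'   when none).
#' @examples
#' classify_pattern(data.frame(fvc_pct = 95, fev1_pct = 60, ratio = 0.55))
#' @export
classify_pattern <- function(indices, config = spiro_config()) {
  stopifnot(is.data.frame(indices),
            all(c("fvc_pct", "fev1_pct", "ratio") %in% names(indices)))
  fvc <- indices$fvc_pct
  fev1 <- indices$fev1_pct
  ratio <- indices$ratio
  if (any(is.na(fvc) | is.na(fev1) | is.na(ratio))) {
    stop("indices contain missing values", call. = FALSE)
  }
  if (any(ratio < 0 | ratio > 1)) {
    stop("FEV1/FVC ratio outside [0, 1]", call. = FALSE)
  }
  if (any(fvc < 0 | fev1 < 0)) {
    stop("percent-of-predicted values must be non-negative", call. = FALSE)
  }
  thr <- config$pct_threshold
  rthr <- config$ratio_threshold

  low_ratio <- ratio < rthr
  low_fvc <- fvc < thr
  pattern <- ifelse(low_ratio,
                    ifelse(low_fvc, "mixed", "obstructive"),
                    ifelse(low_fvc, "spirometric_restriction", "normal"))

  flags <- character(length(pattern))
  add_flag <- function(flags, cond, code) {
    ifelse(cond, ifelse(nzchar(flags), paste(flags, code, sep = ";"), code),
           flags)
  }
  flags <- add_flag(flags, fvc == thr, "BOUNDARY_FVC_80")
  flags <- add_flag(flags, pattern == "normal" & fev1 < thr,
                    "NONSPECIFIC_LOW_FEV1")
  flags <- add_flag(flags, pattern == "mixed" & fev1 >= thr,
                    "MIXED_PRESERVED_FEV1")

  data.frame(pattern = factor(pattern, levels = PATTERN_LEVELS),
             flags = flags, stringsAsFactors = FALSE)
}

#' Grade severity of airflow limitation
#'
#' Severity is quantified by the degree of reduction of the index relevant
#' to the pattern, as percent of predicted: FEV1% for obstructive and mixed
#' patterns, FVC% for spirometric restriction. A normal pattern has no
#' severity grade. Bands (on the chosen index x, half-open so every value
#' gets exactly one grade): mild x >= 70, moderate 60 <= x < 70, moderately
#' severe 50 <= x < 60, severe 35 <= x < 50, very severe x < 35.
#'
#' @param pattern factor/character vector of patterns (as from
#'   [classify_pattern()]).
#' @param indices data.frame of derived indices, same length.
#' @param config a [spiro_config()] object.
#' @return data.frame with columns `severity` (factor) and `index_used`
#'   (`"FEV1"`, `"FVC"` or `"none"`).
#' @examples
#' grade_severity("obstructive", data.frame(fvc_pct = 95, fev1_pct = 65,
#'                                          ratio = 0.55))  # moderate
#' @export
grade_severity <- function(pattern, indices, config = spiro_config()) {
  pattern <- as.character(pattern)
  if (!all(pattern %in% PATTERN_LEVELS)) {
    stop("unknown pattern label(s): ",
         paste(unique(setdiff(pattern, PATTERN_LEVELS)), collapse = ", "),
         call. = FALSE)
  }
  index_used <- ifelse(pattern == "normal", "none",
                       ifelse(pattern == "spirometric_restriction", "FVC",
                              "FEV1"))
  x <- ifelse(index_used == "FEV1", indices$fev1_pct,
              ifelse(index_used == "FVC", indices$fvc_pct, NA_real_))
  b <- config$severity_breaks  # c(35, 50, 60, 70) by default
  grade <- ifelse(index_used == "none", "not_applicable",
           ifelse(x >= b[4], "mild",
           ifelse(x >= b[3], "moderate",
           ifelse(x >= b[2], "moderately_severe",
           ifelse(x >= b[1], "severe", "very_severe")))))
  data.frame(severity = factor(grade, levels = SEVERITY_LEVELS),
             index_used = index_used, stringsAsFactors = FALSE)
}

#' Evaluate the bronchodilator (reversibility) test
#'
#' Compares post- against pre-bronchodilator volumes. The test is positive
#' when FEV1 or FVC improves by at least 12% of its pre-bronchodilator
#' value AND at least 0.2 L (each index is evaluated separately; either
#' suffices). An improvement below the percent threshold is "not
#' significant"; no improvement at all is "negative/unmodified". Records
#' without post-bronchodilator values are "not evaluable".
#'
#' @param records a [spiro_records] object.
#' @param config a [spiro_config()] object.
#' @return data.frame with columns `bd_result` (factor), `delta_fev1_L`,
#'   `delta_fev1_pct`, `delta_fvc_L`, `delta_fvc_pct` (deltas are
#'   post minus pre; percent deltas relative to the pre value; NA when the
#'   post value is absent).
#' @examples
#' r <- spiro_records(data.frame(subject_id = "S1", fvc_pre_L = 4,
#'                               fev1_pre_L = 2, fvc_post_L = 4,
#'                               fev1_post_L = 2.3, fvc_pred_L = 4.5,
#'                               fev1_pred_L = 3.4))
#' evaluate_bronchodilator(r)  # positive: +0.3 L, +15%
#' @export
evaluate_bronchodilator <- function(records, config = spiro_config()) {
  if (!inherits(records, "spiro_records")) records <- spiro_records(records)
  n <- nrow(records)
  fvc_post <- if ("fvc_post_L" %in% names(records)) records$fvc_post_L
              else rep(NA_real_, n)
  fev1_post <- if ("fev1_post_L" %in% names(records)) records$fev1_post_L
               else rep(NA_real_, n)

  d_fev1 <- fev1_post - records$fev1_pre_L
  d_fvc <- fvc_post - records$fvc_pre_L
  d_fev1_pct <- 100 * d_fev1 / records$fev1_pre_L
  d_fvc_pct <- 100 * d_fvc / records$fvc_pre_L

  pos_fev1 <- !is.na(d_fev1) & d_fev1 >= config$bd_abs_threshold_L &
    d_fev1_pct >= config$bd_pct_threshold
  pos_fvc <- !is.na(d_fvc) & d_fvc >= config$bd_abs_threshold_L &
    d_fvc_pct >= config$bd_pct_threshold
  best_pct <- pmax(ifelse(is.na(d_fev1_pct), -Inf, d_fev1_pct),
                   ifelse(is.na(d_fvc_pct), -Inf, d_fvc_pct))

  evaluable <- !is.na(fev1_post) | !is.na(fvc_post)
  result <- ifelse(!evaluable, "not_evaluable",
            ifelse(pos_fev1 | pos_fvc, "positive",
            ifelse(best_pct > 0, "not_significant", "negative_unmodified")))

  data.frame(
    bd_result = factor(result, levels = BD_LEVELS),
    delta_fev1_L = d_fev1, delta_fev1_pct = d_fev1_pct,
    delta_fvc_L = d_fvc, delta_fvc_pct = d_fvc_pct
  )
}

#' Interpret spirometry records
#'
#' The full interpretation pipeline: derives the indices, classifies the
#' pattern, grades severity, and evaluates the bronchodilator test for
#' every record. Pattern and severity are computed from PRE-bronchodilator
#' values; the interpretation is a pure function of the record and the
#' configuration.
#'
#' @param records a [spiro_records] object, or a data.frame coercible to
#'   one.
#' @param config a [spiro_config()] object.
#' @param mode input mode, see [spiro_records()].
#' @param predictor optional reference-value provider: a
#'   `function(sex, age, height, weight)` returning a list or data.frame
#'   with elements `fvc_pred_L` and `fev1_pred_L`, used to fill in
#'   predicted values for records that lack them. None is shipped.
#' @return a `spiro_report` object: a data.frame with one row per record
#'   carrying the subject id, derived indices, pattern, flags, severity,
#'   grading index, bronchodilator result and deltas.
#' @examples
#' rec <- data.frame(subject_id = "S1", fvc_pre_L = 3.8, fev1_pre_L = 2.0,
#'                   fvc_post_L = 3.8, fev1_post_L = 2.3,
#'                   fvc_pred_L = 4.0, fev1_pred_L = 3.2)
#' interpret(rec)
#' @export
interpret <- function(records, config = spiro_config(),
                      mode = c("volumes", "percent"), predictor = NULL) {
  if (!inherits(records, "spiro_records")) {
    if (!is.null(predictor) && is.data.frame(records)) {
      records <- apply_predictor(records, predictor)
    }
    records <- spiro_records(records, mode = match.arg(mode))
  }
  idx <- derive_indices(records)
  pat <- classify_pattern(idx, config)
  sev <- grade_severity(pat$pattern, idx, config)
  bd <- evaluate_bronchodilator(records, config)

  report <- data.frame(
    subject_id = records$subject_id,
    fvc_pct = idx$fvc_pct, fev1_pct = idx$fev1_pct, ratio = idx$ratio,
    pattern = pat$pattern, flags = pat$flags,
    severity = sev$severity, severity_index = sev$index_used,
    bd_result = bd$bd_result,
    delta_fev1_L = bd$delta_fev1_L, delta_fev1_pct = bd$delta_fev1_pct,
    delta_fvc_L = bd$delta_fvc_L, delta_fvc_pct = bd$delta_fvc_pct,
    stringsAsFactors = FALSE
  )
  structure(report, class = c("spiro_report", "data.frame"),
            config = config)
}

# Fill missing predicted values from a user-registered reference predictor.
apply_predictor <- function(data, predictor) {
  stopifnot(is.function(predictor))
  need_cols <- c("sex", "age", "height", "weight")
  if (!all(need_cols %in% names(data))) {
    stop("a reference predictor needs columns ",
         paste(need_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("fvc_pred_L", "fev1_pred_L")) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }
  miss <- is.na(data$fvc_pred_L) | is.na(data$fev1_pred_L)
  if (any(miss)) {
    pred <- predictor(data$sex[miss], data$age[miss], data$height[miss],
                      data$weight[miss])
    data$fvc_pred_L[miss] <- pred$fvc_pred_L
    data$fev1_pred_L[miss] <- pred$fev1_pred_L
  }
  data
}

#' @export
print.spiro_report <- function(x, n = 10L, ...) {
  cat(sprintf("Spirometry interpretation report: %d record(s)\n", nrow(x)))
  shown <- utils::head(x, n)
  out <- data.frame(
    subject = shown$subject_id,
    `FVC%` = sprintf("%.1f", shown$fvc_pct),
    `FEV1%` = sprintf("%.1f", shown$fev1_pct),
    ratio = sprintf("%.2f", shown$ratio),
    pattern = as.character(shown$pattern),
    severity = as.character(shown$severity),
    BD = as.character(shown$bd_result),
    flags = shown$flags,
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... and %d more record(s)\n", nrow(x) - n))
  invisible(x)
}

#' @export
summary.spiro_report <- function(object, ...) {
  out <- list(
    n = nrow(object),
    pattern = table(object$pattern),
    severity = table(object$severity),
    bd = table(object$bd_result),
    flagged = sum(nzchar(object$flags))
  )
  class(out) <- "summary.spiro_report"
  out
}

#' @export
print.summary.spiro_report <- function(x, ...) {
  cat(sprintf("Interpretation of %d spirometry record(s)\n\n", x$n))
  cat("Pattern:\n"); print(x$pattern)
  cat("\nSeverity:\n"); print(x$severity)
  cat("\nBronchodilator test:\n"); print(x$bd)
  cat(sprintf("\n%d record(s) carry boundary/non-specific flags\n", x$flagged))
  invisible(x)
}

#' Write an interpretation report
#'
#' `write_report_json()` writes one JSON object per record (pattern,
#' severity, bronchodilator result, indices, flags); `write_report_csv()`
#' writes the flat tabular summary. Percent values are rendered to 1
#' decimal in both formats; thresholds were applied at full precision
#' beforehand.
#'
#' @param report a `spiro_report` from [interpret()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "spiro_report"))
  out <- lapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    list(
      subject_id = r$subject_id,
      pattern = as.character(r$pattern),
      severity = as.character(r$severity),
      severity_index = r$severity_index,
      bd_test = as.character(r$bd_result),
      indices = list(fvc_pct = round(r$fvc_pct, 1),
                     fev1_pct = round(r$fev1_pct, 1),
                     ratio = round(r$ratio, 2)),
      flags = if (nzchar(r$flags)) strsplit(r$flags, ";")[[1]] else character()
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "spiro_report"))
  df <- as.data.frame(report)
  for (col in c("fvc_pct", "fev1_pct", "delta_fev1_pct", "delta_fvc_pct")) {
    df[[col]] <- round(df[[col]], 1)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
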