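#' Construct and validate a set of spirometry records
#'
#' A spirometry record holds one subject's anthropometrics plus the pre-
#' and (optionally) post-bronchodilator absolute FVC and FEV1 in litres and
#' the predicted values they are compared against. Validation enforces the
#' physiological invariants: FEV1 cannot exceed FVC (it is a sub-volume),
#' all volumes must be finite and non-negative, and predicted values must
#' be strictly positive.
#'
#' Two input modes are supported. In `"volumes"` mode (default) the columns
#' `fvc_pred_L` and `fev1_pred_L` carry predicted volumes and percent of
#' predicted is derived. In `"percent"` mode the columns `fvc_pct` and
#' `fev1_pct` carry percent-of-predicted directly (the absolute pre-
#' bronchodilator volumes are still required for the FEV1/FVC ratio and the
#' bronchodilator deltas).
#'
#' @param data a data.frame with columns `subject_id`, `fvc_pre_L`,
#'   `fev1_pre_L`, and either `fvc_pred_L` + `fev1_pred_L` (volumes mode) or
#'   `fvc_pct` + `fev1_pct` (percent mode). Optional columns: `sex`
#'   ("male"/"female"), `age` (years), `height` (cm), `weight` (kg),
#'   `fvc_post_L`, `fev1_post_L`. Extra columns are carried through
#'   untouched.
#' @param mode `"volumes"` or `"percent"`, see Details.
#' @return the validated data.frame with class `spiro_records` and the mode
#'   stored as an attribute.
#' @seealso [read_spiro_csv()], [read_spiro_jsonl()], [interpret()]
#' @examples
#' spiro_records(data.frame(
#'   subject_id = "S1", fvc_pre_L = 3.2, fev1_pre_L = 2.6,
#'   fvc_pred_L = 4.0, fev1_pred_L = 3.1
#' ))
#' @export
spiro_records <- function(data, mode = c("volumes", "percent")) {
  mode <- match.arg(mode)
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  required <- c("subject_id", "fvc_pre_L", "fev1_pre_L")
  required <- c(required, if (mode == "volumes") c("fvc_pred_L", "fev1_pred_L")
                          else c("fvc_pct", "fev1_pct"))
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  num_cols <- intersect(
    c("fvc_pre_L", "fev1_pre_L", "fvc_post_L", "fev1_post_L",
      "fvc_pred_L", "fev1_pred_L", "fvc_pct", "fev1_pct",
      "age", "height", "weight"),
    names(data)
  )
  for (col in num_cols) {
    if (!is.numeric(data[[col]])) {
      bad <- which(!grepl("^\\s*-?[0-9.eE+-]*\\s*$", as.character(data[[col]])))
      stop(sprintf("column `%s` is not numeric%s", col,
                   if (length(bad)) paste0(" (first offending row: ", bad[1], ")")
                   else ""),
           call. = FALSE)
    }
  }

  fail <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop(sprintf("invalid record(s) in row(s) %s: %s",
                   paste(utils::head(rows, 5L), collapse = ", "), what),
           call. = FALSE)
    }
  }
  isna <- function(x) is.na(x)
  finite_or_na <- function(x) is.na(x) | is.finite(x)

  fail(isna(data$fvc_pre_L) | isna(data$fev1_pre_L),
       "pre-bronchodilator FVC and FEV1 are required")
  for (col in num_cols) {
    fail(!finite_or_na(data[[col]]), sprintf("`%s` must be finite", col))
  }
  fail(data$fvc_pre_L < 0 | data$fev1_pre_L < 0,
       "pre-bronchodilator volumes must be non-negative")
  fail(data$fev1_pre_L > data$fvc_pre_L,
       "fev1_pre_L exceeds fvc_pre_L (FEV1 is a sub-volume of FVC)")
  if (mode == "volumes") {
    fail(isna(data$fvc_pred_L) | data$fvc_pred_L <= 0,
         "`fvc_pred_L` must be strictly positive")
    fail(isna(data$fev1_pred_L) | data$fev1_pred_L <= 0,
         "`fev1_pred_L` must be strictly positive")
  } else {
    fail(isna(data$fvc_pct) | data$fvc_pct < 0, "`fvc_pct` must be >= 0")
    fail(isna(data$fev1_pct) | data$fev1_pct < 0, "`fev1_pct` must be >= 0")
  }
  if ("fvc_post_L" %in% names(data) || "fev1_post_L" %in% names(data)) {
    post_fvc <- if ("fvc_post_L" %in% names(data)) data$fvc_post_L else NA_real_
    post_fev1 <- if ("fev1_post_L" %in% names(data)) data$fev1_post_L else NA_real_
    fail(!is.na(post_fvc) & post_fvc < 0, "`fvc_post_L` must be non-negative")
    fail(!is.na(post_fev1) & post_fev1 < 0, "`fev1_post_L` must be non-negative")
    fail(!is.na(post_fev1) & data$fev1_pre_L == 0,
         "post-bronchodilator FEV1 present but pre-bronchodilator FEV1 is 0 (percent change undefined)")
    fail(!is.na(post_fvc) & data$fvc_pre_L == 0,
         "post-bronchodilator FVC present but pre-bronchodilator FVC is 0 (percent change undefined)")
  }
  if ("sex" %in% names(data)) {
    fail(!is.na(data$sex) & !data$sex %in% c("male", "female"),
         "`sex` must be \"male\" or \"female\"")
  }
  for (col in intersect(c("age", "height", "weight"), names(data))) {
    fail(!is.na(data[[col]]) & data[[col]] <= 0,
         sprintf("`%s` must be strictly positive", col))
  }

  structure(data, class = c("spiro_records", "data.frame"), mode = mode)
}

#' Derive the interpretation indices from spirometry records
#'
#' Computes, per record, the three quantities the pattern classifier works
#' on: FVC percent of predicted, FEV1 percent of predicted, and the
#' absolute FEV1/FVC ratio. All three are computed from PRE-bronchodilator
#' volumes at full precision; no rounding is applied before threshold
#' comparisons.
#'
#' @param records a [spiro_records] object (or data.frame accepted by it).
#' @param mode passed to [spiro_records()] when `records` is a bare
#'   data.frame; ignored otherwise.
#' @return data.frame with columns `fvc_pct`, `fev1_pct`, `ratio`.
#' @examples
#' r <- spiro_records(data.frame(subject_id = "S1", fvc_pre_L = 3.2,
#'                               fev1_pre_L = 2.6, fvc_pred_L = 4.0,
#'                               fev1_pred_L = 3.1))
#' derive_indices(r)  # fvc_pct 80, fev1_pct ~83.9, ratio 0.8125
#' @export
derive_indices <- function(records, mode = c("volumes", "percent")) {
  if (!inherits(records, "spiro_records")) {
    records <- spiro_records(records, mode = match.arg(mode))
  }
  mode <- attr(records, "mode")
  if (any(records$fvc_pre_L == 0)) {
    stop("invalid record(s) in row(s) ",
         paste(utils::head(which(records$fvc_pre_L == 0), 5L), collapse = ", "),
         ": `fvc_pre_L` is 0, FEV1/FVC ratio undefined", call. = FALSE)
  }
  if (mode == "volumes") {
    fvc_pct <- 100 * records$fvc_pre_L / records$fvc_pred_L
    fev1_pct <- 100 * records$fev1_pre_L / records$fev1_pred_L
  } else {
    fvc_pct <- records$fvc_pct
    fev1_pct <- records$fev1_pct
  }
  data.frame(
    fvc_pct = fvc_pct,
    fev1_pct = fev1_pct,
    ratio = records$fev1_pre_L / records$fvc_pre_L
  )
}

#' Read spirometry records from a CSV file
#'
#' One row per subject; the header must use the canonical column names of
#' [spiro_records()]. Malformed rows are reported with their row numbers.
#'
#' @param path path to the CSV file.
#' @inheritParams spiro_records
#' @return a validated [spiro_records] object.
#' @export
read_spiro_csv <- function(path, mode = c("volumes", "percent")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  spiro_records(df, mode = match.arg(mode))
}

#' Read spirometry records from a JSON-lines file
#'
#' One JSON object per line with the same keys as the CSV columns.
#'
#' @inheritParams read_spiro_csv
#' @return a validated [spiro_records] object.
#' @export
read_spiro_jsonl <- function(path, mode = c("volumes", "percent")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records in ", path, call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop(sprintf(
                      "line %d: invalid JSON (%s)", i, conditionMessage(e)),
                      call. = FALSE))
    as.data.frame(obj, stringsAsFactors = FALSE)
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  spiro_records(do.call(rbind, rows), mode = match.arg(mode))
}
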