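#' Cross-tabulate two raters' categorical calls
#'
#' Builds the square contingency table of paired calls: rows are rater A,
#' columns rater B. Pairs where either call is missing are dropped
#' (pairwise deletion), matching how agreement is computed when raters
#' omit calls on some cases.
#'
#' @param a,b equal-length vectors of category labels (NA = omitted call).
#' @param categories category universe, in display order. Defaults to the
#'   sorted union of observed labels; at least two categories are required.
#' @return a `contingency_table`: an integer matrix with both dimnames set
#'   to `categories` and attribute `n` (total pairs kept).
#' @examples
#' cross_tab(c("normal", "mixed", "normal"),
#'           c("normal", "mixed", "mixed"),
#'           categories = c("normal", "obstructive",
#'                          "spirometric_restriction", "mixed"))
#' @export
cross_tab <- function(a, b, categories = NULL) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  a <- as.character(a); b <- as.character(b)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no complete pairs of calls", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  if (length(categories) < 2L) {
    stop("at least two categories are required", call. = FALSE)
  }
  bad <- setdiff(unique(c(a, b)), categories)
  if (length(bad)) {
    stop("label(s) outside the category set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- table(factor(a, levels = categories), factor(b, levels = categories))
  m <- matrix(as.integer(m), nrow = length(categories),
              dimnames = list(rater_a = categories, rater_b = categories))
  contingency_table(m)
}

#' @rdname cross_tab
#' @param counts a square non-negative integer matrix (rows rater A,
#'   columns rater B) with identical row and column names.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2L) {
    stop("`counts` must be a square matrix with k >= 2 categories",
         call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts)) ||
      !identical(rownames(counts), colnames(counts))) {
    stop("`counts` needs identical row and column category names",
         call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty contingency table", call. = FALSE)
  structure(counts, n = sum(counts),
            class = c("contingency_table", "matrix", "array"))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table (%d x %d, n = %d)\n",
              nrow(x), ncol(x), attr(x, "n")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Merge categories of a contingency table
#'
#' Sums rows and columns according to a mapping from old to new category
#' names; the total count is preserved. Used, e.g., to fold the mixed
#' pattern into the obstructive one when a rater does not distinguish
#' them.
#'
#' @param x a `contingency_table`.
#' @param merge_map named character vector mapping old category names to
#'   new ones. Categories not named map to themselves; the merged table
#'   keeps the first-appearance order of new names.
#' @return a `contingency_table` over the merged categories.
#' @examples
#' t4 <- study_tables()$table3_pulm2
#' merge_categories(t4, c(mixed = "obstructive"))
#' @export
merge_categories <- function(x, merge_map) {
  stopifnot(inherits(x, "contingency_table"))
  old <- rownames(x)
  if (is.null(names(merge_map)) || any(!nzchar(names(merge_map)))) {
    stop("`merge_map` must be a named character vector (old -> new)",
         call. = FALSE)
  }
  unknown <- setdiff(names(merge_map), old)
  if (length(unknown)) {
    stop("merge_map names not in the table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  new <- ifelse(old %in% names(merge_map), merge_map[old], old)
  new_levels <- unique(new)
  if (length(new_levels) < 2L) {
    stop("merging would leave fewer than two categories", call. = FALSE)
  }
  agg <- matrix(0L, length(new_levels), length(new_levels),
                dimnames = list(rater_a = new_levels, rater_b = new_levels))
  for (i in seq_along(old)) {
    for (j in seq_along(old)) {
      agg[new[i], new[j]] <- agg[new[i], new[j]] + x[i, j]
    }
  }
  contingency_table(agg)
}

#' Pool severity grades into three groups
#'
#' Pools the five severity grades for agreement analysis: (1) mild,
#' (2) moderate to moderately severe, (3) severe to very severe. A
#' `not_applicable` grade (normal pattern) has no pooled group and maps to
#' NA so the case is excluded pairwise downstream.
#'
#' @param severity character or factor vector of severity grades.
#' @return factor over the three pooled groups (NA for excluded cases).
#' @examples
#' pool_severity(c("mild", "moderately_severe", "very_severe"))
#' @export
pool_severity <- function(severity) {
  severity <- as.character(severity)
  bad <- setdiff(unique(severity[!is.na(severity)]), SEVERITY_LEVELS)
  if (length(bad)) {
    stop("unknown severity grade(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pooled <- c(mild = "mild",
              moderate = "moderate_to_moderately_severe",
              moderately_severe = "moderate_to_moderately_severe",
              severe = "severe_to_very_severe",
              very_severe = "severe_to_very_severe",
              not_applicable = NA_character_)[severity]
  factor(unname(pooled), levels = POOLED_SEVERITY_LEVELS)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement over a square contingency table:
#' kappa = (po - pe) / (1 - pe) with po the observed diagonal proportion
#' and pe the agreement expected from the marginals. The standard error is
#' the Fleiss-Cohen-Everitt asymptotic formula and the confidence interval
#' the symmetric Wald interval, deliberately uncapped (upper endpoints may
#' exceed 1, as commonly printed for near-perfect agreement).
#'
#' @param x a `contingency_table`, a plain square matrix of counts, or a
#'   vector of rater-A labels (then `y` must hold rater B's labels).
#' @param y rater-B labels when `x` is a label vector.
#' @param categories optional category universe for label input.
#' @param conf_level confidence level, default 0.95.
#' @return object of class `kappa_result` with elements `kappa`, `se`,
#'   `ci_low`, `ci_high`, `po`, `pe`, `n`, `k` (categories), `label`
#'   (Landis-Koch band) and `conf_level`.
#' @examples
#' cohen_kappa(study_tables()$table3_pulm1)  # 0.885
#' @export
cohen_kappa <- function(x, y = NULL, categories = NULL, conf_level = 0.95) {
  if (!is.null(y)) {
    x <- cross_tab(x, y, categories)
  } else if (!inherits(x, "contingency_table")) {
    x <- contingency_table(x)
  }
  n <- sum(x)
  p <- x / n
  po <- sum(diag(p))
  r <- rowSums(p)
  cl <- colSums(p)
  pe <- sum(r * cl)
  if (pe >= 1) {
    stop("degenerate marginals: expected agreement is 1, kappa undefined",
         call. = FALSE)
  }
  kappa <- unname((po - pe) / (1 - pe))

  # Fleiss, Cohen & Everitt asymptotic variance of kappa-hat; cancellation
  # can leave a tiny negative value at extreme tables, clamped to 0
  a_term <- sum(diag(p) * (1 - (r + cl) * (1 - kappa))^2)
  b_term <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (i != j) b_term <- b_term + p[i, j] * (cl[i] + r[j])^2
    }
  }
  b_term <- (1 - kappa)^2 * b_term
  c_term <- (kappa - pe * (1 - kappa))^2
  se <- unname(sqrt(max(0, a_term + b_term - c_term) / n) / (1 - pe))

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(kappa = kappa, se = se,
         ci_low = kappa - z * se, ci_high = kappa + z * se,
         po = po, pe = pe, n = n, k = nrow(x),
         label = landis_koch(kappa), conf_level = conf_level,
         table = x),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, digits = 3, ...) {
  cat(sprintf("Cohen's kappa: %.*f (%.0f%% CI %.*f-%.*f)\n",
              digits, x$kappa, 100 * x$conf_level,
              digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  n = %d pairs over %d categories; po = %.3f, pe = %.3f\n",
              x$n, x$k, x$po, x$pe))
  cat(sprintf("  Landis-Koch: %s agreement\n", gsub("_", " ", x$label)))
  invisible(x)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Bands: <= 0 none; (0, 0.20] slight; (0.20, 0.40] fair; (0.40, 0.60]
#' moderate; (0.60, 0.80] substantial; (0.80, 1] almost perfect.
#'
#' @param kappa numeric vector of kappa values (<= 1).
#' @return character vector of band labels.
#' @examples
#' landis_koch(c(0.907, 0.5, 0))
#' @export
landis_koch <- function(kappa) {
  stopifnot(is.numeric(kappa), all(kappa <= 1 + 1e-12))
  out <- ifelse(kappa <= 0, "none",
         ifelse(kappa <= 0.20, "slight",
         ifelse(kappa <= 0.40, "fair",
         ifelse(kappa <= 0.60, "moderate",
         ifelse(kappa <= 0.80, "substantial", "almost_perfect")))))
  out
}

#' Intra-rater reliability from repeated calls
#'
#' Cohen's kappa of one rater against their own blinded repeat calls on
#' the same cases. Pairs where either call is missing are dropped.
#'
#' @param first,repeated equal-length vectors of the rater's first and
#'   repeat calls.
#' @inheritParams cohen_kappa
#' @return a `kappa_result`.
#' @examples
#' intra_rater_kappa(c("normal", "mixed", "normal"),
#'                   c("normal", "mixed", "normal"),
#'                   categories = c("normal", "mixed"))  # kappa 1
#' @export
intra_rater_kappa <- function(first, repeated, categories = NULL,
                              conf_level = 0.95) {
  cohen_kappa(first, repeated, categories = categories,
              conf_level = conf_level)
}
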