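#' Interpretation thresholds and reporting options
#'
#' Collects every tunable threshold of the interpretation algorithm in one
#' validated object. Defaults are the fixed-ratio SEPAR/ATS-ERS convention:
#' FEV1/FVC below 0.70 signals obstruction, volumes below 80% of predicted
#' are reduced, and a bronchodilator response is positive when FEV1 or FVC
#' improves by at least 12% of the pre-bronchodilator value and at least
#' 0.2 L.
#'
#' @param ratio_threshold FEV1/FVC ratio below which airflow is considered
#'   obstructed (absolute value, default 0.70). The fixed ratio is the
#'   convention implemented here; age-dependent lower-limit-of-normal
#'   thresholds can be emulated per record by supplying a different value.
#' @param pct_threshold percent-of-predicted value below which FVC or FEV1
#'   is considered reduced (default 80).
#' @param severity_breaks increasing vector of four percent-of-predicted
#'   cut points separating very severe / severe / moderately severe /
#'   moderate / mild impairment (default \code{c(35, 50, 60, 70)}). Each
#'   break belongs to the band above it: exactly 70 is mild, exactly 35 is
#'   severe.
#' @param bd_pct_threshold minimum percent improvement over the
#'   pre-bronchodilator value for a positive bronchodilator test
#'   (default 12).
#' @param bd_abs_threshold_L minimum absolute improvement in litres for a
#'   positive bronchodilator test (default 0.2).
#' @param conf_level confidence level used by downstream statistics
#'   (default 0.95).
#'
#' @return An object of class \code{spiro_config}.
#' @examples
#' spiro_config()
#' spiro_config(ratio_threshold = 0.65)
#' @export
spiro_config <- function(ratio_threshold = 0.7,
                         pct_threshold = 80,
                         severity_breaks = c(35, 50, 60, 70),
                         bd_pct_threshold = 12,
                         bd_abs_threshold_L = 0.2,
                         conf_level = 0.95) {
  stopifnot(
    is.numeric(ratio_threshold), length(ratio_threshold) == 1L,
    ratio_threshold > 0, ratio_threshold < 1,
    is.numeric(pct_threshold), length(pct_threshold) == 1L, pct_threshold > 0,
    is.numeric(severity_breaks), length(severity_breaks) == 4L,
    all(diff(severity_breaks) > 0), all(severity_breaks > 0),
    is.numeric(bd_pct_threshold), bd_pct_threshold > 0,
    is.numeric(bd_abs_threshold_L), bd_abs_threshold_L > 0,
    is.numeric(conf_level), conf_level > 0, conf_level < 1
  )
  structure(
    list(
      ratio_threshold = ratio_threshold,
      pct_threshold = pct_threshold,
      severity_breaks = severity_breaks,
      bd_pct_threshold = bd_pct_threshold,
      bd_abs_threshold_L = bd_abs_threshold_L,
      conf_level = conf_level
    ),
    class = "spiro_config"
  )
}

#' @export
print.spiro_config <- function(x, ...) {
  cat("Spirometry interpretation configuration\n")
  cat(sprintf("  FEV1/FVC obstruction threshold : < %.2f\n", x$ratio_threshold))
  cat(sprintf("  Reduced volume threshold       : < %g%% of predicted\n",
              x$pct_threshold))
  cat(sprintf("  Severity bands (%% predicted)   : <%g | %g-%g | %g-%g | %g-%g | >=%g\n",
              x$severity_breaks[1], x$severity_breaks[1], x$severity_breaks[2],
              x$severity_breaks[2], x$severity_breaks[3], x$severity_breaks[3],
              x$severity_breaks[4], x$severity_breaks[4]))
  cat(sprintf("  Positive bronchodilator test   : >= %g%% and >= %g L\n",
              x$bd_pct_threshold, x$bd_abs_threshold_L))
  cat(sprintf("  Confidence level               : %.2f\n", x$conf_level))
  invisible(x)
}
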