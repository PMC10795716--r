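#' Bundled validation-study contingency tables
#'
#' The published cross-tabulations of the app-validation study, shipped as
#' plain-text fixtures (see `inst/extdata/README.md`): the two dichotomous
#' (normal/impaired) 2x2 tables of the app against each pulmonologist, the
#' 3x3 four-level-pattern table against pulmonologist 1 (who folded mixed
#' into obstructive), and the full 4x4 table against pulmonologist 2. All
#' four sum to the study's 118 spirometries. Rows are the app's calls,
#' columns the pulmonologist's.
#'
#' @return named list of [contingency_table] objects:
#'   `table1_pulm1`, `table1_pulm2`, `table3_pulm1`, `table3_pulm2`; each
#'   carries a `description` attribute with its provenance.
#' @examples
#' tabs <- study_tables()
#' sum(tabs$table1_pulm1)           # 118
#' cohen_kappa(tabs$table3_pulm2)   # 0.923
#' @export
study_tables <- function() {
  read_fixture <- function(file, description) {
    path <- system.file("extdata", file, package = "spirointerp",
                        mustWork = TRUE)
    m <- as.matrix(utils::read.delim(path, row.names = 1,
                                     check.names = FALSE))
    colnames(m) <- rownames(m)  # guard against header mangling
    tab <- contingency_table(m)
    attr(tab, "description") <- description
    tab
  }
  list(
    table1_pulm1 = read_fixture(
      "table1_pulmonologist1.tsv",
      "dichotomous pattern calls, app vs pulmonologist 1 (n = 118)"),
    table1_pulm2 = read_fixture(
      "table1_pulmonologist2.tsv",
      "dichotomous pattern calls, app vs pulmonologist 2 (n = 118)"),
    table3_pulm1 = read_fixture(
      "table3_pulmonologist1.tsv",
      "pattern calls (mixed folded into obstructive), app vs pulmonologist 1 (n = 118)"),
    table3_pulm2 = read_fixture(
      "table3_pulmonologist2.tsv",
      "four-level pattern calls, app vs pulmonologist 2 (n = 118)")
  )
}

# A 2x2 contingency table of dichotomous calls (rows = test, cols = gold)
# recast as a confusion table with "impaired" the positive class.
confusion_from_table <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"),
            identical(rownames(tab), DICHOTOMY_LEVELS))
  confusion_2x2(tp = tab["impaired", "impaired"],
                fp = tab["impaired", "normal"],
                fn = tab["normal", "impaired"],
                tn = tab["normal", "normal"])
}

#' Reproduce the validation-study statistics from the bundled tables
#'
#' Recomputes, from the shipped contingency tables alone, the study's
#' headline results: the seven diagnostic-accuracy statistics of the app
#' against each pulmonologist (sensitivity, specificity, PPV, NPV, both
#' likelihood ratios, overall accuracy, plus the single-threshold AUC),
#' the four-level-pattern Cohen's kappas against both pulmonologists, and
#' the dichotomous-pattern kappas. Every statistic carries its interval
#' and a method tag. The computation is fully deterministic.
#'
#' @param conf_level confidence level for every interval, default 0.95.
#' @return object of class `study_reproduction`: a list with elements
#'   `accuracy` (two [diag_accuracy] objects), `pattern_kappa` and
#'   `dichotomous_kappa` (two [cohen_kappa()] results each), and `tables`.
#' @examples
#' rs <- reproduce_study()
#' rs$accuracy$pulmonologist1
#' rs$pattern_kappa$pulmonologist1$kappa  # 0.885
#' @export
reproduce_study <- function(conf_level = 0.95) {
  tabs <- study_tables()
  conf1 <- confusion_from_table(tabs$table1_pulm1)
  conf2 <- confusion_from_table(tabs$table1_pulm2)
  out <- list(
    accuracy = list(
      pulmonologist1 = diag_accuracy(conf1, conf_level),
      pulmonologist2 = diag_accuracy(conf2, conf_level)
    ),
    pattern_kappa = list(
      pulmonologist1 = cohen_kappa(tabs$table3_pulm1, conf_level = conf_level),
      pulmonologist2 = cohen_kappa(tabs$table3_pulm2, conf_level = conf_level)
    ),
    dichotomous_kappa = list(
      pulmonologist1 = cohen_kappa(tabs$table1_pulm1, conf_level = conf_level),
      pulmonologist2 = cohen_kappa(tabs$table1_pulm2, conf_level = conf_level)
    ),
    tables = tabs,
    conf_level = conf_level
  )
  class(out) <- "study_reproduction"
  out
}

#' @export
print.study_reproduction <- function(x, ...) {
  cat("Validation-study reproduction from the bundled contingency tables\n")
  cat("================================================================\n\n")
  for (who in c("pulmonologist1", "pulmonologist2")) {
    cat(sprintf("-- App vs %s --\n", who))
    print(x$accuracy[[who]])
    pk <- x$pattern_kappa[[who]]
    dk <- x$dichotomous_kappa[[who]]
    cat(sprintf("  Pattern kappa (%d categories): %.3f (%.3f-%.3f)\n",
                pk$k, pk$kappa, pk$ci_low, pk$ci_high))
    cat(sprintf("  Dichotomous kappa:             %.3f (%.3f-%.3f)\n\n",
                dk$kappa, dk$ci_low, dk$ci_high))
  }
  invisible(x)
}
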