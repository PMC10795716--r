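test_that("dichotomization maps the three impaired patterns to impaired", {
  got <- dichotomize_pattern(c("normal", "obstructive",
                               "spirometric_restriction", "mixed"))
  expect_equal(as.character(got), c("normal", "impaired", "impaired",
                                    "impaired"))
  expect_error(dichotomize_pattern("obstr"), "unknown pattern")
})

test_that("build_confusion counts paired labels and is length-checked", {
  test <- c("impaired", "impaired", "normal", "normal", "impaired")
  gold <- c("impaired", "normal", "normal", "impaired", "impaired")
  cm <- build_confusion(test, gold)
  expect_equal(cm$tp, 2); expect_equal(cm$fp, 1)
  expect_equal(cm$fn, 1); expect_equal(cm$tn, 1)
  expect_error(build_confusion(test, gold[-1]), "same length")
  # all-agree input has no off-diagonal counts
  agree <- build_confusion(test, test)
  expect_equal(agree$fp, 0); expect_equal(agree$fn, 0)
})

test_that("swapping rater roles exchanges fp and fn but fixes tp and tn", {
  set.seed(11)
  for (i in 1:20) {
    a <- sample(c("normal", "impaired"), 40, replace = TRUE)
    b <- sample(c("normal", "impaired"), 40, replace = TRUE)
    ab <- build_confusion(a, b)
    ba <- build_confusion(b, a)
    expect_equal(ba$tp, ab$tp); expect_equal(ba$tn, ab$tn)
    expect_equal(ba$fp, ab$fn); expect_equal(ba$fn, ab$fp)
  }
})

test_that("accuracy statistics reproduce the published validation values", {
  cms <- table1_confusions()
  a1 <- diag_accuracy(cms$pulm1)
  expect_equal(get_stat(a1, "sensitivity"), 97.5, tolerance = 1e-6)
  expect_equal(round(get_stat(a1, "specificity"), 1), 94.9)
  expect_equal(round(get_stat(a1, "ppv"), 1), 90.7)
  expect_equal(round(get_stat(a1, "npv"), 1), 98.7)
  expect_equal(round(get_stat(a1, "plr"), 2), 19.01)
  expect_equal(round(get_stat(a1, "nlr"), 2), 0.03)
  expect_equal(round(get_stat(a1, "accuracy"), 1), 95.8)

  a2 <- diag_accuracy(cms$pulm2)
  expect_equal(get_stat(a2, "sensitivity"), 100)
  expect_equal(round(get_stat(a2, "specificity"), 1), 98.7)
  expect_equal(round(get_stat(a2, "ppv"), 1), 97.7)
  expect_equal(get_stat(a2, "npv"), 100)
  expect_equal(get_stat(a2, "plr"), 76)
  expect_equal(get_stat(a2, "nlr"), 0)
  expect_equal(round(get_stat(a2, "accuracy"), 1), 99.2)
})

test_that("predictive-value intervals match the published logit intervals", {
  cms <- table1_confusions()
  a1 <- diag_accuracy(cms$pulm1)
  expect_equal(round(get_stat(a1, "ppv", "ci_low"), 1), 78.9)
  expect_equal(round(get_stat(a1, "ppv", "ci_high"), 1), 96.2)
  expect_equal(round(get_stat(a1, "npv", "ci_low"), 1), 91.4)
  expect_equal(round(get_stat(a1, "npv", "ci_high"), 1), 99.8)
  expect_equal(get_stat(a1, "ppv", "ci_method"), "mercaldo_logit")
  a2 <- diag_accuracy(cms$pulm2)
  expect_equal(round(get_stat(a2, "ppv", "ci_low"), 1), 85.7)
  expect_equal(round(get_stat(a2, "ppv", "ci_high"), 1), 99.7)
  # NPV is exactly 100%: the logit interval is undefined there and the
  # Wilson continuity-corrected fallback is used
  expect_equal(get_stat(a2, "npv", "ci_method"), "wilson_cc")
  expect_equal(round(get_stat(a2, "npv", "ci_low"), 1), 93.9)
  expect_equal(get_stat(a2, "npv", "ci_high"), 100)
})

test_that("Clopper-Pearson endpoints match tail-inversion on many tables", {
  cases <- rbind(c(0, 10), c(10, 10), c(39, 40), c(74, 78), c(1, 40),
                 c(55, 113), c(3, 7), c(117, 118))
  for (i in seq_len(nrow(cases))) {
    k <- cases[i, 1]; n <- cases[i, 2]
    expect_equal(clopper_pearson(k, n), ref_clopper_pearson(k, n),
                 tolerance = 1e-7, info = sprintf("k=%d n=%d", k, n))
  }
  # boundary behaviour
  expect_equal(clopper_pearson(0, 20)[1], 0)
  expect_equal(clopper_pearson(20, 20)[2], 1)
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  for (n in c(5, 10, 20, 30)) {
    ints <- t(vapply(0:n, function(k) clopper_pearson(k, n), numeric(2)))
    for (p in seq(0.05, 0.95, by = 0.05)) {
      inside <- ints[, 1] <= p & p <= ints[, 2]
      coverage <- sum(stats::dbinom(0:n, n, p)[inside])
      expect_gte(coverage, 0.95)
    }
  }
})

test_that("likelihood-ratio log-method CI agrees with a parametric bootstrap", {
  # counts large enough for the delta-method premise; the bootstrap is the
  # model-free reference
  cm <- confusion_2x2(tp = 120, fp = 80, fn = 40, tn = 240)
  lrs <- likelihood_ratios(cm)
  plr_row <- lrs[lrs$statistic == "plr", ]
  expect_equal(plr_row$estimate, 0.75 / 0.25)

  set.seed(99)
  B <- 1e5
  s_boot <- rbinom(B, 160, 0.75) / 160
  sp_boot <- rbinom(B, 320, 0.75) / 320
  plr_boot <- s_boot / (1 - sp_boot)
  q <- unname(quantile(plr_boot, c(0.025, 0.975)))
  # delta-method interval vs percentile bootstrap: within 10% on log scale
  expect_lt(abs(log(plr_row$ci_low / q[1])), 0.10)
  expect_lt(abs(log(plr_row$ci_high / q[2])), 0.10)

  nlr_row <- lrs[lrs$statistic == "nlr", ]
  expect_equal(nlr_row$estimate, 0.25 / 0.75)
  nlr_boot <- (1 - s_boot) / sp_boot
  qn <- unname(quantile(nlr_boot, c(0.025, 0.975)))
  expect_lt(abs(log(nlr_row$ci_low / qn[1])), 0.10)
  expect_lt(abs(log(nlr_row$ci_high / qn[2])), 0.10)
})

test_that("degenerate tables give infinite or zero likelihood ratios", {
  perfect <- confusion_2x2(tp = 20, fp = 0, fn = 0, tn = 30)
  lrs <- likelihood_ratios(perfect)
  expect_equal(lrs$estimate[lrs$statistic == "plr"], Inf)
  expect_equal(lrs$estimate[lrs$statistic == "nlr"], 0)
  expect_equal(lrs$ci_high[lrs$statistic == "plr"], Inf)
})

test_that("+LR exceeds 1 exactly when agreement beats the chance level", {
  set.seed(31)
  for (i in 1:200) {
    cts <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))
    cm <- confusion_2x2(tp = cts[1], fp = cts[2], fn = cts[3], tn = cts[4])
    if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) next
    acc <- diag_accuracy(cm)
    sens <- get_stat(acc, "sensitivity"); spec <- get_stat(acc, "specificity")
    if (sens %in% c(0, 100) || spec %in% c(0, 100)) next
    n <- attr(cm, "n")
    po <- (cm$tp + cm$tn) / n
    pe <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
             (cm$fp + cm$tn) * (cm$fn + cm$tn)) / n^2
    expect_equal(get_stat(acc, "plr") > 1, po > pe)
    # weighted identity: accuracy is the prevalence-weighted mean of
    # sensitivity and specificity
    expect_equal(get_stat(acc, "accuracy"),
                 (sens * (cm$tp + cm$fn) + spec * (cm$tn + cm$fp)) / n)
    # proportions stay inside [0, 100]
    props <- acc$estimate[acc$statistic %in%
                            c("sensitivity", "specificity", "ppv", "npv",
                              "accuracy")]
    expect_true(all(props >= 0 & props <= 100))
  }
})

test_that("single-threshold AUC equals the mean of sens and spec", {
  perfect <- confusion_2x2(tp = 20, fp = 0, fn = 0, tn = 30)
  expect_equal(binary_auc(perfect)$estimate, 1)
  coin <- confusion_2x2(tp = 10, fp = 15, fn = 10, tn = 15)
  expect_equal(binary_auc(coin)$estimate, 0.5)
  set.seed(5)
  for (i in 1:25) {
    cts <- rmultinom(1, 150, prob = runif(4, 0.1, 1))
    cm <- confusion_2x2(tp = cts[1], fp = cts[2], fn = cts[3], tn = cts[4])
    sens <- cm$tp / (cm$tp + cm$fn); spec <- cm$tn / (cm$tn + cm$fp)
    # explicit two-point trapezoid over (0,0), (1-spec, sens), (1,1)
    x <- c(0, 1 - spec, 1); y <- c(0, sens, 1)
    trap <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    expect_equal(binary_auc(cm)$estimate, trap, tolerance = 1e-12)
  }
})

test_that("proportion-precision planning formula behaves as documented", {
  expect_equal(required_sample_size(0.5, 0.5), 4L)
  expect_equal(required_sample_size(0.9, 0.07), 71L)
  # halving the half-width quadruples n (up to ceiling effects)
  n1 <- required_sample_size(0.3, 0.1)
  n2 <- required_sample_size(0.3, 0.05)
  expect_lt(abs(n2 / n1 - 4), 0.05)
})

test_that("empty gold-standard classes are rejected", {
  expect_error(diag_accuracy(confusion_2x2(tp = 0, fp = 5, fn = 0, tn = 10)),
               "gold-standard")
})
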