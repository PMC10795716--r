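test_that("cross_tab reconstructs the published 4x4 table from raw labels", {
  tab <- study_tables()$table3_pulm2
  # expand the printed counts back into label pairs, shuffle, re-tabulate
  app <- rep(rownames(tab)[row(tab)], tab)
  pulm <- rep(colnames(tab)[col(tab)], tab)
  set.seed(4)
  ord <- sample(length(app))
  rebuilt <- cross_tab(app[ord], pulm[ord], categories = pattern_levels)
  expect_equal(unclass(rebuilt)[pattern_levels, pattern_levels],
               unclass(tab)[pattern_levels, pattern_levels],
               ignore_attr = TRUE)
  expect_equal(attr(rebuilt, "n"), 118)
  expect_equal(diag(unclass(rebuilt)), c(normal = 75, obstructive = 11,
                                         spirometric_restriction = 14,
                                         mixed = 13))
})

test_that("cross_tab validates its input", {
  expect_error(cross_tab(character(), character()), "no complete pairs")
  expect_error(cross_tab("a", c("a", "b")), "same length")
  expect_error(cross_tab(c("a", "a"), c("a", "a")), "at least two categories")
  expect_error(cross_tab(c("a", "zz"), c("a", "b"),
                         categories = c("a", "b")), "zz")
})

test_that("merging categories preserves the total and sums cells", {
  t4 <- study_tables()$table3_pulm2
  merged <- merge_categories(t4, c(mixed = "obstructive"))
  expect_equal(dim(merged), c(3L, 3L))
  expect_equal(sum(merged), 118)
  expect_equal(merged["obstructive", "obstructive"],
               t4["obstructive", "obstructive"] + t4["mixed", "mixed"] +
                 t4["obstructive", "mixed"] + t4["mixed", "obstructive"])
  # identity map leaves the table unchanged
  ident <- merge_categories(t4, c(mixed = "mixed"))
  expect_equal(unclass(ident), unclass(t4), ignore_attr = TRUE)
  # conservation under random merges of random tables
  set.seed(12)
  for (i in 1:25) {
    m <- matrix(rpois(16, 5), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
    tab <- contingency_table(m)
    target <- sample(letters[1:4], 1)
    victim <- sample(setdiff(letters[1:4], target), 1)
    mm <- merge_categories(tab, stats::setNames(target, victim))
    expect_equal(sum(mm), sum(tab))
  }
})

test_that("severity pooling follows the three published groups", {
  expect_equal(as.character(pool_severity("mild")), "mild")
  expect_equal(as.character(pool_severity(c("moderate", "moderately_severe"))),
               rep("moderate_to_moderately_severe", 2))
  expect_equal(as.character(pool_severity(c("severe", "very_severe"))),
               rep("severe_to_very_severe", 2))
  # a normal pattern has no severity group; the case is excluded
  expect_true(is.na(pool_severity("not_applicable")))
  expect_error(pool_severity("grim"), "unknown severity")
})

test_that("kappa reproduces the published agreement coefficients", {
  tabs <- study_tables()
  k1 <- cohen_kappa(tabs$table3_pulm1)
  expect_equal(round(k1$kappa, 3), 0.885)
  expect_equal(k1$label, "almost_perfect")
  k2 <- cohen_kappa(tabs$table3_pulm2)
  expect_equal(round(k2$kappa, 3), 0.923)
  kd1 <- cohen_kappa(tabs$table1_pulm1)
  expect_equal(round(kd1$kappa, 3), 0.907)
  kd2 <- cohen_kappa(tabs$table1_pulm2)
  expect_equal(round(kd2$kappa, 3), 0.982)
})

test_that("asymptotic kappa intervals match the published ones to 0.01", {
  tabs <- study_tables()
  printed <- list(
    table3_pulm1 = c(0.803, 0.967),
    table3_pulm2 = c(0.858, 0.987),
    table1_pulm1 = c(0.826, 0.987),
    table1_pulm2 = c(0.946, 1.017)  # uncapped upper endpoint above 1
  )
  for (nm in names(printed)) {
    k <- cohen_kappa(tabs[[nm]])
    expect_lt(abs(k$ci_low - printed[[nm]][1]), 0.01)
    expect_lt(abs(k$ci_high - printed[[nm]][2]), 0.01)
  }
  expect_gt(cohen_kappa(tabs$table1_pulm2)$ci_high, 1)
})

test_that("kappa equals the label-list definition on small inputs", {
  cats <- c("x", "y")
  # exhaustive over all pairs of binary label lists of length 4
  grids <- expand.grid(rep(list(cats), 4), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grids))) {
    a <- unlist(grids[i, ])
    for (j in seq_len(nrow(grids))) {
      b <- unlist(grids[j, ])
      po <- mean(a == b)
      pe <- mean(a == "x") * mean(b == "x") + mean(a == "y") * mean(b == "y")
      if (pe >= 1) {
        expect_error(cohen_kappa(a, b, categories = cats), "degenerate")
      } else {
        expect_equal(cohen_kappa(a, b, categories = cats)$kappa,
                     ref_kappa_from_labels(a, b, cats))
      }
    }
  }
  # random longer lists up to n = 12
  set.seed(8)
  for (r in 1:50) {
    n <- sample(5:12, 1)
    a <- sample(cats, n, replace = TRUE)
    b <- sample(cats, n, replace = TRUE)
    pe <- mean(a == "x") * mean(b == "x") + mean(a == "y") * mean(b == "y")
    if (pe >= 1) next
    expect_equal(cohen_kappa(a, b, categories = cats)$kappa,
                 ref_kappa_from_labels(a, b, cats))
  }
})

test_that("kappa is 1 iff all off-diagonal counts vanish", {
  perfect <- contingency_table(matrix(c(10, 0, 0, 7), 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("a", "b"))))
  expect_equal(cohen_kappa(perfect)$kappa, 1)
  expect_equal(cohen_kappa(perfect)$se, 0)
  set.seed(21)
  for (i in 1:50) {
    m <- matrix(rpois(9, 3), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    if (sum(m) == 0) next
    tab <- contingency_table(m)
    pe_ok <- tryCatch({cohen_kappa(tab); TRUE}, error = function(e) FALSE)
    if (!pe_ok) next
    k <- cohen_kappa(tab)$kappa
    expect_equal(isTRUE(all.equal(k, 1)), sum(m) == sum(diag(m)))
  }
})

test_that("kappa is invariant under simultaneous category permutation", {
  tab <- study_tables()$table3_pulm2
  set.seed(3)
  for (i in 1:10) {
    perm <- sample(nrow(tab))
    permuted <- contingency_table(unclass(tab)[perm, perm])
    expect_equal(cohen_kappa(permuted)$kappa, cohen_kappa(tab)$kappa)
    expect_equal(cohen_kappa(permuted)$se, cohen_kappa(tab)$se)
  }
})

test_that("the Wald interval is symmetric about the estimate and uncapped", {
  k <- cohen_kappa(study_tables()$table1_pulm2)
  expect_equal(k$ci_high - k$kappa, k$kappa - k$ci_low)
  expect_gt(k$ci_high, 1)
})

test_that("Landis-Koch bands assign boundary values to the lower band", {
  expect_equal(landis_koch(c(0.907, 0.5, 0)), c("almost_perfect", "moderate",
                                                "none"))
  expect_equal(landis_koch(c(0.2, 0.4, 0.6, 0.8, 1)),
               c("slight", "fair", "moderate", "substantial",
                 "almost_perfect"))
  expect_equal(landis_koch(-0.3), "none")
})

test_that("intra-rater kappa of identical repeat calls is 1", {
  calls <- sample(pattern_levels, 30, replace = TRUE)
  k <- intra_rater_kappa(calls, calls, categories = pattern_levels)
  expect_equal(k$kappa, 1)
  # omitted repeat calls are dropped pairwise
  repeated <- calls
  repeated[1:5] <- NA
  k2 <- intra_rater_kappa(calls, repeated, categories = pattern_levels)
  expect_equal(k2$n, 25)
  expect_equal(k2$kappa, 1)
})

test_that("known flip-rate repeats recover the expected intra-rater kappa", {
  set.seed(14)
  eps <- 0.1
  n <- 5000
  cats <- c("normal", "impaired")
  first <- sample(cats, n, replace = TRUE, prob = c(0.65, 0.35))
  flip <- runif(n) < eps
  repeated <- ifelse(flip, ifelse(first == "normal", "impaired", "normal"),
                     first)
  k <- intra_rater_kappa(first, repeated, categories = cats)
  # closed-form expectation via the flip model's confusion matrix
  C <- matrix(c(1 - eps, eps, eps, 1 - eps), 2, 2,
              dimnames = list(cats, cats))
  k_exp <- expected_kappa(c(0.65, 0.35), rater_model(C))
  expect_lt(abs(k$kappa - k_exp), 3 * k$se)
})

test_that("degenerate marginals give an undefined-kappa error", {
  m <- matrix(c(5, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(cohen_kappa(contingency_table(m)), "undefined")
})

test_that("contingency table fixtures validate their shape", {
  expect_error(contingency_table(matrix(1:6, 2, 3)), "square")
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("b", "a")))
  expect_error(contingency_table(m), "identical row and column")
  m2 <- matrix(c(1, -1, 0, 2), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(contingency_table(m2), "non-negative")
})
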