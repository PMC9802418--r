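test_that("Spearman correlation matches Pearson-on-ranks brute force", {
  expect_equal(spearman_rho(1:5, 1:5)$rho, 1)
  expect_equal(spearman_rho(1:5, 5:1)$rho, -1)
  # 4 swapped neighbour pairs: 1 - 6*4/(5*24) = 0.8, confirmed by the
  # rank-Pearson oracle below
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5))$rho,
               oracle_spearman(1:5, c(2, 1, 4, 3, 5)))

  set.seed(301)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    x <- sample(1:10, n, replace = TRUE)  # ties exercised
    y <- rnorm(n)
    if (sd(x) == 0) next
    expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }

  # invariant under strictly monotone transforms of either argument
  set.seed(302)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, base)
  expect_equal(spearman_rho(x, y^3)$rho, base)

  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("multilevel-lesion rules match their definitions exhaustively", {
  # CDACE: all 16 inflamed-quartile subsets against the stated rule
  subsets <- as.matrix(expand.grid(q1 = c(FALSE, TRUE), q2 = c(FALSE, TRUE),
                                   q3 = c(FALSE, TRUE), q4 = c(FALSE, TRUE)))
  got <- multilevel_lesion(subsets, "CDACE")
  want <- apply(subsets, 1, function(z) {
    idx <- which(z)
    length(idx) >= 2 && !(length(idx) == 2 && idx[2] - idx[1] == 1)
  })
  expect_identical(unname(got), unname(want))
  # adjacent pairs excluded, non-adjacent pairs included
  expect_false(multilevel_lesion(c(TRUE, TRUE, FALSE, FALSE), "CDACE"))
  expect_true(multilevel_lesion(c(TRUE, FALSE, TRUE, FALSE), "CDACE"))

  # LS: more than 2 of 3 tertiles
  expect_false(multilevel_lesion(c(TRUE, TRUE, FALSE), "LS"))
  expect_true(multilevel_lesion(c(TRUE, TRUE, TRUE), "LS"))
  # CECDAI: both segments
  expect_false(multilevel_lesion(c(TRUE, FALSE), "CECDAI"))
  expect_true(multilevel_lesion(c(TRUE, TRUE), "CECDAI"))

  expect_error(multilevel_lesion(c(TRUE, TRUE), "CDACE"), "4 regions")
  expect_error(multilevel_lesion(c(TRUE, NA, TRUE, TRUE), "CDACE"),
               "missing")
})

test_that("ROC cutoff selection agrees with the exhaustive-threshold oracle", {
  r <- roc_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$cutoff, 2.5)
  expect_equal(r$auc, 1)
  expect_equal(c(r$sensitivity, r$specificity, r$ppv, r$npv), c(1, 1, 1, 1))

  set.seed(501)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    scores <- sample(1:12, n, replace = TRUE)
    labels <- runif(n) < 0.5
    if (all(labels) || !any(labels)) next
    got <- roc_cutoff(as.numeric(scores), labels)
    want <- oracle_roc(as.numeric(scores), labels)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$auc, want$auc, tolerance = 1e-12)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$ppv, want$ppv)
    expect_equal(got$npv, want$npv)
  }

  expect_error(roc_cutoff(1:5, rep(TRUE, 5)), "degenerate")
})

test_that("ROC AUC equals the Mann-Whitney normalization and pROC on tie-free data", {
  skip_if_not_installed("pROC")
  set.seed(502)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    scores <- rnorm(n)  # tie-free almost surely
    labels <- runif(n) < 0.5
    if (all(labels) || !any(labels)) next
    got <- roc_cutoff(scores, labels)$auc
    u <- mean(outer(scores[labels], scores[!labels], ">"))
    expect_equal(got, u, tolerance = 1e-12)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("labels independent of exchangeable scores give AUC near 1/2", {
  set.seed(503)
  aucs <- replicate(200, {
    scores <- rnorm(40)
    labels <- sample(rep(c(TRUE, FALSE), 20))
    roc_cutoff(scores, labels)$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("ICC(2,1) matches the hand ANOVA decomposition", {
  # identical readers, varying subjects: perfect agreement
  m_perfect <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc_2_1(m_perfect)$icc, 1)

  # tiny matrix against the aov-based oracle and the closed-form 8/9
  m <- matrix(c(1, 3, 5, 2, 4, 6), ncol = 2)
  expect_equal(icc_2_1(m)$icc, 8 / 9, tolerance = 1e-12)
  expect_equal(icc_2_1(m)$icc, oracle_icc21(m), tolerance = 1e-10)

  set.seed(601)
  for (i in 1:20) {
    n <- sample(3:10, 1); k <- sample(2:5, 1)
    mm <- matrix(rnorm(n * k, 5, 2), n, k) + rnorm(n)  # subject effects
    expect_equal(icc_2_1(mm)$icc, oracle_icc21(mm), tolerance = 1e-10)
  }

  # shift invariance
  set.seed(602)
  mm <- matrix(rnorm(30), 10, 3) + rnorm(10)
  expect_equal(icc_2_1(mm)$icc, icc_2_1(mm + 100)$icc, tolerance = 1e-10)

  expect_error(icc_2_1(matrix(1, 4, 3)), "zero total variance")
  expect_error(icc_2_1(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("ICC(2,1) interval matches an independent reference implementation", {
  # 6x3 matrix frozen from a seeded draw; expected estimate and 95% CI were
  # computed with an independent reference implementation of the
  # Shrout-Fleiss two-way random absolute-agreement ICC
  m <- matrix(c(
    5.4279250044, 5.9593162691, 5.1756574099, 5.8877170150, 4.2743241590,
    5.2453480590, 3.2723096237, 5.9792485334, 4.2717661749, 2.4115159866,
    3.5084619091, 6.8431007240, 6.5001087008, -0.0171080318, -1.0818681907,
    5.0005316011, 4.2119620115, 1.5099446784), nrow = 6)
  r <- icc_2_1(m)
  expect_equal(r$icc, -0.230882, tolerance = 1e-5)
  expect_equal(r$ci_low, -0.388176, tolerance = 1e-5)
  expect_equal(r$ci_high, 0.330146, tolerance = 1e-5)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
})

test_that("Shapiro-Wilk wrapper behaves as a normality screen", {
  set.seed(701)
  p_norm <- replicate(20, normality_check(rnorm(100))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_skew <- replicate(20, normality_check(rexp(200))$p_value)
  expect_gte(mean(p_skew < 0.05), 0.9)
  expect_error(normality_check(rep(2, 10)), "constant")
  expect_error(normality_check(1:2), "3..5000")
})

test_that("tidiers and plots expose the result objects", {
  r <- roc_cutoff(c(1, 2, 3, 4, 5, 6), c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
  g <- glance(r)
  expect_s3_class(g, "tbl_df")
  expect_named(g, c("cutoff", "auc", "sensitivity", "specificity", "ppv",
                    "npv", "youden", "n_pos", "n_neg"))
  expect_s3_class(tidy(r), "tbl_df")
  expect_s3_class(autoplot(r), "ggplot")

  m <- matrix(rnorm(30), 10, 3) + rnorm(10)
  ic <- icc_2_1(m)
  expect_named(glance(ic), c("icc", "ci_low", "ci_high", "n_subjects",
                             "k_readers", "conf_level"))
  expect_identical(tidy(ic)$term, c("subject", "reader", "error"))

  sc <- score_cdace(make_study("a", c(3, 1, 0, 2), traversed = TRUE))
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(plot_quartile_grades(sc), "ggplot")
})
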