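test_that("wilcoxon signed-rank: direction, symmetry, degenerate input", {
  # symmetric differences (+1, -1, +2, -2) -> Z = 0
  res <- wilcoxon_signed_rank(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(res$statistic, 0)
  # scores rising from a to b -> negative Z
  res <- wilcoxon_signed_rank(1:8, (1:8) + 2)
  expect_lt(res$statistic, 0)
  expect_lt(res$p.value, 0.05)
  # all differences zero
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  # zeros are dropped before ranking
  res <- wilcoxon_signed_rank(c(5, 5, 1, 2, 3), c(5, 5, 0, 0, 0))
  expect_identical(res$n, 3L)
})

test_that("wilcoxon normal approximation tracks exact sign-flip enumeration", {
  # all-positive differences 1..6: only 1 of 2^6 assignments reaches W+ = 21
  probs <- wplus_null_distribution(1:6)
  expect_equal(sum(probs[22:22]), 1 / 64)
  expect_equal(sum(probs), 1)

  # approximation quality on tie-free random instances, n = 10..15
  set.seed(421)
  for (rep in 1:20) {
    n <- sample(10:15, 1)
    d <- round(stats::rnorm(n, mean = 0.4, sd = 1), 6)
    d <- d[d != 0]
    if (length(d) < 10 || anyDuplicated(abs(d))) next
    res <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_lt(abs(res$p.value - exact_wilcoxon_p(d)), 0.02)
  }
})

test_that("wilcoxon Z and p agree with the base-R normal approximation", {
  set.seed(7)
  a <- sample(3:12, 40, replace = TRUE)
  b <- sample(3:12, 40, replace = TRUE)
  keep <- a != b
  res <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a[keep], b[keep], paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$w_pos, unname(ref$statistic))
})

test_that("spearman rank correlation: worked values and t-approximation p", {
  expect_equal(spearman_rank_correlation(c(1, 2, 3), c(10, 20, 30))$estimate, 1)
  expect_equal(spearman_rank_correlation(c(1, 2, 3), c(30, 20, 10))$estimate, -1)
  res <- spearman_rank_correlation(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(res$estimate, 0.8)
  ref <- stats::cor.test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4),
                         method = "spearman", exact = FALSE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  expect_error(spearman_rank_correlation(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(spearman_rank_correlation(1:2, 1:2), "at least 3")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(11)
  for (rep in 1:10) {
    x <- stats::rnorm(20)
    y <- x + stats::rnorm(20)
    base <- spearman_rank_correlation(x, y)$estimate
    expect_equal(spearman_rank_correlation(exp(x), y)$estimate, base)
    expect_equal(spearman_rank_correlation(x, y^3)$estimate, base)
  }
})

test_that("roc curve: worked examples and shape invariants", {
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(rep(5, 6), c(0, 1, 0, 1, 1, 0))$auc, 0.5)
  curve <- roc_curve(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1))
  expect_equal(curve$auc, 5 / 6)
  # sensitivity non-increasing as the cutoff rises; fractions in [0, 1]
  expect_true(all(diff(curve$points$sensitivity) <= 0))
  expect_true(all(curve$points$sensitivity >= 0 &
                    curve$points$sensitivity <= 1))
  expect_true(all(curve$points$specificity >= 0 &
                    curve$points$specificity <= 1))
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "single class")
})

test_that("trapezoidal AUC equals Mann-Whitney pair enumeration", {
  set.seed(2024)
  for (rep in 1:60) {
    n <- sample(4:30, 1)
    scores <- sample(0:12, n, replace = TRUE)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(scores, labels)$auc,
                 auc_pair_enumeration(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on an integer-score instance", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- sample(3:12, 60, replace = TRUE)
  labels <- as.integer(scores + sample(-2:2, 60, replace = TRUE) > 7)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_curve(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("prevalence-weighted accuracy is a convex combination", {
  expect_equal(prevalence_weighted_accuracy(1, 1, 10, 90), 1)
  # sens = spec = s -> accuracy = s regardless of prevalence
  for (prev in c(0.1, 0.5, 0.9)) {
    expect_equal(prevalence_weighted_accuracy(0.7, 0.7, prev, 1 - prev), 0.7)
  }
  set.seed(3)
  for (rep in 1:25) {
    se <- stats::runif(1); sp <- stats::runif(1)
    np <- sample(1:50, 1); nn <- sample(1:50, 1)
    acc <- prevalence_weighted_accuracy(se, sp, np, nn)
    expect_gte(acc, min(se, sp) - 1e-12)
    expect_lte(acc, max(se, sp) + 1e-12)
  }
  expect_error(prevalence_weighted_accuracy(0.5, 0.5, -1, 2), "non-negative")
  expect_error(prevalence_weighted_accuracy(1.2, 0.5, 1, 1), "\\[0, 1\\]")
})

test_that("operating characteristics at a fixed cutoff", {
  oc <- operating_characteristics(c(1, 2, 3, 4), c(0, 0, 1, 1), 3)
  expect_equal(oc$sensitivity, 1)
  expect_equal(oc$specificity, 1)
  expect_equal(oc$accuracy, 1)
  oc <- operating_characteristics(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1), 4)
  expect_equal(oc$sensitivity, 2 / 3)
  expect_equal(oc$specificity, 1)
})

test_that("Youden cutoff maximizes J with ties broken to the lower cutoff", {
  curve <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  op <- best_cutoff_youden(curve)
  expect_equal(op$cutoff, 3)
  expect_equal(op$youden, 1)
  # uninformative scores -> J = 0
  op <- best_cutoff_youden(roc_curve(rep(2, 8), rep(c(0, 1), 4)))
  expect_equal(op$youden, 0)
  # exhaustive-scan example
  op <- best_cutoff_youden(roc_curve(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1)))
  expect_equal(op$cutoff, 4)
  expect_equal(op$sensitivity, 2 / 3)
  expect_equal(op$specificity, 1)
})

test_that("quadratic-weighted kappa: worked values and degeneracy", {
  expect_equal(quadratic_weighted_kappa(c(0, 1, 2, 1), c(0, 1, 2, 1))$kappa, 1)
  res <- quadratic_weighted_kappa(c(0, 1, 2, 1), c(0, 2, 2, 1))
  expect_equal(res$kappa, 0.8)
  expect_identical(res$weighting, "quadratic")
  expect_error(quadratic_weighted_kappa(c(1, 1, 1), c(1, 1, 1),
                                        categories = 0:2), "degenerate")
  expect_error(quadratic_weighted_kappa(c(1, 1, 1), c(1, 1, 1)),
               "at least 2 categories")
  expect_error(quadratic_weighted_kappa(c(0, 1), c(0, 3), categories = 0:2),
               "outside")
})

test_that("kappa is symmetric and matches a direct confusion-matrix oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    a <- sample(0:3, n, replace = TRUE)
    b <- pmin(pmax(a + sample(-1:1, n, replace = TRUE), 0), 3)
    if (length(unique(c(a, b))) < 2) next
    ka <- quadratic_weighted_kappa(a, b, categories = 0:3)$kappa
    expect_equal(ka, qwk_direct(a, b, 0:3), tolerance = 1e-12)
    expect_equal(ka, quadratic_weighted_kappa(b, a, categories = 0:3)$kappa,
                 tolerance = 1e-12)
  }
  # independently shuffled ratings at large n -> kappa near 0
  set.seed(123)
  a <- sample(0:2, 4000, replace = TRUE)
  b <- sample(0:2, 4000, replace = TRUE)
  expect_lt(abs(quadratic_weighted_kappa(a, b, categories = 0:2)$kappa), 0.05)
})

test_that("Cohen's d and magnitude bands", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_identical(cohens_d(c(1, 2, 3), c(1, 2, 3))$magnitude, "negligible")
  # means 1 apart at unit pooled SD -> d = 1, large
  set.seed(1)
  a <- stats::rnorm(5000)
  res <- cohens_d(a, a + 1)
  expect_equal(res$d, 1, tolerance = 0.05)
  expect_identical(cohens_d(c(0, 1, 2), c(1, 2, 3))$magnitude, "large")
  expect_identical(effect_magnitude(c(0.1, 0.3, 0.6, 1.0, 1.3, 1.4)),
                   c("negligible", "small", "medium", "large", "large",
                     "very large"))
  expect_error(cohens_d(c(2, 2, 2), c(2, 2, 2)), "degenerate")
})

test_that("VAS dichotomization at the pain threshold", {
  expect_identical(dichotomize_vas(c(0, 2, 3, 10)), c(0L, 0L, 1L, 1L))
  expect_error(dichotomize_vas(11), "vas")
  expect_error(dichotomize_vas(-1), "vas")
})
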