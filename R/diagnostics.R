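# Validity statistics implemented from their definitions: paired Wilcoxon
# signed-rank (normal approximation with tie correction), Spearman rank
# correlation, empirical ROC curves, prevalence-weighted accuracy,
# quadratic-weighted kappa, and Cohen effect sizes with magnitude bands.

#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Tests whether paired scores differ in location. Zero differences are
#' discarded before ranking (the classical treatment); absolute differences
#' are ranked with average ranks for ties, and the positive-rank sum
#' `W+` is standardized with the tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48`, with a continuity correction of
#' one half toward the mean (the convention of standard clinical
#' statistics software; it keeps the approximation within 0.02 of the
#' exact sign-flip p down to 10 informative pairs). The sign of Z follows
#' the direction of `a - b`, so scores rising from `a` to `b` give a
#' negative Z.
#'
#' @param a,b Numeric vectors of paired scores, equal length.
#' @return A list with `statistic` (Z), `p.value` (two-sided, standard
#'   normal), `n` (pairs remaining after zero removal) and `w_pos` (the
#'   positive-rank sum).
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8), c(3, 4, 5, 6))
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("'a' and 'b' must be numeric", call. = FALSE)
  }
  check_equal_lengths(a, b)
  if (anyNA(a) || anyNA(b)) stop("paired samples contain NA", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("degenerate input: all paired differences are zero", call. = FALSE)
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_sizes <- as.vector(table(abs(d)))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_sizes^3 - tie_sizes) / 48
  if (sigma2 <= 0) {
    stop("degenerate input: zero variance of the rank sum", call. = FALSE)
  }
  dev <- w_pos - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  list(statistic = z, p.value = min(1, 2 * stats::pnorm(-abs(z))), n = n,
       w_pos = w_pos)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with a two-sided p-value from the
#' t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, equal length of at least 3, each
#'   non-constant.
#' @return A list with `estimate` (rs), `p.value` and `n`.
#' @examples
#' spearman_rank_correlation(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))  # rs = 0.8
#' @export
spearman_rank_correlation <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("'x' and 'y' must be numeric", call. = FALSE)
  }
  check_equal_lengths(x, y)
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("inputs contain NA", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("degenerate input: constant variable", call. = FALSE)
  }
  rs <- stats::cor(rank(x), rank(y))
  if (abs(rs) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(estimate = rs, p.value = p, n = n)
}

#' Empirical ROC curve for a pain score against a binary reference
#'
#' Positivity rule is `score >= cutoff` (higher scores indicate more
#' pain). One operating point is produced per distinct observed score,
#' plus a sentinel above the maximum so the curve runs from sensitivity 1
#' / specificity 0 down to sensitivity 0 / specificity 1. The AUC is the
#' trapezoidal area under the empirical curve, which equals the
#' Mann-Whitney statistic with ties counted one half.
#'
#' @param scores Numeric score vector.
#' @param labels Binary reference vector (0/1 or logical), same length;
#'   both classes must be present.
#' @return An object of class `roc_curve`: a list with `points` (tibble of
#'   cutoff, sensitivity, specificity, sorted by cutoff), `auc`, `n_pos`,
#'   `n_neg`.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
#' @seealso [best_cutoff_youden()], [operating_characteristics()]
#' @export
roc_curve <- function(scores, labels) {
  if (!is.numeric(scores)) stop("'scores' must be numeric", call. = FALSE)
  labels <- as.integer(labels)
  check_equal_lengths(scores, labels)
  if (anyNA(scores) || anyNA(labels)) stop("inputs contain NA", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) {
    stop("'labels' must be binary (0/1)", call. = FALSE)
  }
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("degenerate input: labels contain a single class", call. = FALSE)
  }
  cutoffs <- c(sort(unique(scores)), max(scores) + 1)
  sens <- vapply(cutoffs, function(cc) mean(pos >= cc), numeric(1))
  spec <- vapply(cutoffs, function(cc) mean(neg < cc), numeric(1))
  fpr <- 1 - spec
  k <- length(cutoffs)
  auc <- sum((fpr[-k] - fpr[-1]) * (sens[-k] + sens[-1]) / 2)
  structure(
    list(points = tibble::tibble(cutoff = cutoffs, sensitivity = sens,
                                 specificity = spec),
         auc = auc, n_pos = length(pos), n_neg = length(neg)),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d operating points, %d pos / %d neg, AUC = %.3f\n",
              nrow(x$points), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Prevalence-weighted accuracy
#'
#' Accuracy defined as sensitivity times the prevalence of positives plus
#' specificity times the prevalence of negatives -- i.e. the overall
#' probability of a correct classification at the study's class balance.
#'
#' @param sensitivity,specificity Fractions in `[0, 1]`.
#' @param n_pos,n_neg Non-negative class counts (or class proportions;
#'   only their ratio matters), summing to a positive value.
#' @return Accuracy as a fraction in `[0, 1]`.
#' @examples
#' prevalence_weighted_accuracy(0.765, 0.708, 100, 47)
#' @export
prevalence_weighted_accuracy <- function(sensitivity, specificity, n_pos, n_neg) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must be in [0, 1]", call. = FALSE)
  }
  if (any(n_pos < 0) || any(n_neg < 0)) {
    stop("class counts must be non-negative", call. = FALSE)
  }
  n <- n_pos + n_neg
  if (any(n <= 0)) stop("need at least one observation", call. = FALSE)
  sensitivity * n_pos / n + specificity * n_neg / n
}

#' Sensitivity, specificity and accuracy at a fixed cutoff
#'
#' Applies the positivity rule `score >= cutoff` and reports sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and prevalence-weighted
#' accuracy.
#'
#' @inheritParams roc_curve
#' @param cutoff Score value above (or at) which an observation is called
#'   positive.
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `accuracy`.
#' @export
operating_characteristics <- function(scores, labels, cutoff) {
  if (!is.numeric(scores)) stop("'scores' must be numeric", call. = FALSE)
  labels <- as.integer(labels)
  check_equal_lengths(scores, labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("'labels' must be binary (0/1)", call. = FALSE)
  }
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("degenerate input: labels contain a single class", call. = FALSE)
  }
  sens <- mean(pos >= cutoff)
  spec <- mean(neg < cutoff)
  list(cutoff = cutoff, sensitivity = sens, specificity = spec,
       accuracy = prevalence_weighted_accuracy(sens, spec, length(pos),
                                               length(neg)))
}

#' Youden-optimal operating point of a ROC curve
#'
#' Returns the operating point maximizing Youden's J = sensitivity +
#' specificity - 1, breaking ties toward the lower cutoff (the more
#' sensitive point).
#'
#' @param curve A [roc_curve()] object.
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `youden`
#'   and prevalence-weighted `accuracy` at the curve's class balance.
#' @export
best_cutoff_youden <- function(curve) {
  if (!inherits(curve, "roc_curve")) {
    stop("'curve' must be a roc_curve object", call. = FALSE)
  }
  pts <- curve$points
  j <- pts$sensitivity + pts$specificity - 1
  i <- which(j >= max(j) - 1e-12)[1]
  list(cutoff = pts$cutoff[i],
       sensitivity = pts$sensitivity[i],
       specificity = pts$specificity[i],
       youden = j[i],
       accuracy = prevalence_weighted_accuracy(pts$sensitivity[i],
                                               pts$specificity[i],
                                               curve$n_pos, curve$n_neg))
}

#' Quadratic-weighted Cohen's kappa
#'
#' Chance-corrected agreement between two ordinal raters with weights
#' `w_ij = 1 - ((i - j)/(k - 1))^2`, so disagreements are penalized in
#' proportion to the squared category distance. Expected agreement comes
#' from the product of the marginal distributions.
#'
#' @param ratings_a,ratings_b Equal-length rating vectors (factors or
#'   atomic) over a shared ordered category set.
#' @param categories The ordered category set. Defaults to the factor
#'   levels of `ratings_a` (if a factor) or the sorted distinct values
#'   observed in either rater.
#' @return A list with `kappa`, `weighting = "quadratic"` and `n`.
#' @examples
#' quadratic_weighted_kappa(c(0, 1, 2, 1), c(0, 2, 2, 1))  # 0.8
#' @export
quadratic_weighted_kappa <- function(ratings_a, ratings_b, categories = NULL) {
  if (is.null(categories)) {
    categories <- if (is.factor(ratings_a)) {
      levels(ratings_a)
    } else {
      sort(unique(c(ratings_a, ratings_b)))
    }
  }
  a <- as.character(ratings_a)
  b <- as.character(ratings_b)
  categories <- as.character(categories)
  check_equal_lengths(a, b)
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired ratings", call. = FALSE)
  k <- length(categories)
  if (k < 2L) stop("need at least 2 categories", call. = FALSE)
  ia <- match(a, categories)
  ib <- match(b, categories)
  if (anyNA(ia) || anyNA(ib)) {
    stop("ratings outside the category set", call. = FALSE)
  }
  w <- 1 - (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2
  obs <- table(factor(ia, levels = seq_len(k)),
               factor(ib, levels = seq_len(k))) / n
  p_o <- sum(w * obs)
  p_e <- sum(w * outer(rowSums(obs), colSums(obs)))
  if (1 - p_e < 1e-12) {
    stop("degenerate input: expected agreement is 1 (no rating variation)",
         call. = FALSE)
  }
  list(kappa = (p_o - p_e) / (1 - p_e), weighting = "quadratic", n = n)
}

#' Cohen's d with magnitude bands
#'
#' Standardized mean difference `(mean(b) - mean(a)) / pooled SD`, pooled
#' over both groups with `n - 1` denominators. Magnitude bands on `|d|`:
#' below 0.2 negligible, 0.2-0.5 small, 0.5-0.8 medium, 0.8-1.3 large,
#' above 1.3 very large.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @return A list with `d` and `magnitude`.
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))
#' @export
cohens_d <- function(group_a, group_b) {
  if (!is.numeric(group_a) || !is.numeric(group_b)) {
    stop("groups must be numeric", call. = FALSE)
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (anyNA(group_a) || anyNA(group_b)) stop("groups contain NA", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(group_a) + (n2 - 1) * stats::var(group_b)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    stop("degenerate input: zero pooled standard deviation", call. = FALSE)
  }
  d <- (mean(group_b) - mean(group_a)) / sqrt(sp2)
  list(d = d, magnitude = effect_magnitude(d))
}

#' Cohen magnitude band of an effect size
#'
#' @param d Numeric effect sizes.
#' @return Character vector: `negligible`, `small`, `medium`, `large` or
#'   `very large`.
#' @export
effect_magnitude <- function(d) {
  ad <- abs(d)
  ifelse(ad < 0.2, "negligible",
         ifelse(ad < 0.5, "small",
                ifelse(ad < 0.8, "medium",
                       ifelse(ad <= 1.3, "large", "very large"))))
}

#' Dichotomize the visual analog scale at the pain threshold
#'
#' Self-reported VAS of 3 or more defines presence of pain.
#'
#' @param vas Integer VAS values in 0-10.
#' @param cutoff Positivity threshold, default 3.
#' @return Integer vector of 0/1 pain labels.
#' @examples
#' dichotomize_vas(c(2, 3, 10))  # 0 1 1
#' @export
dichotomize_vas <- function(vas, cutoff = 3) {
  vas <- check_item(vas, "vas", 0L, 10L)
  as.integer(vas >= cutoff)
}
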