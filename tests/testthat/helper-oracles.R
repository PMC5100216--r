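# Independent oracles used to check the package's statistics against
# first-principles computations.

# Exact distribution of the Wilcoxon positive-rank sum W+ under the null,
# by enumeration of all 2^n sign assignments (dynamic programming over the
# integer ranks; requires tie-free |differences|).
wplus_null_distribution <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  stopifnot(all(r == round(r)))
  tot <- sum(r)
  counts <- rep(0, tot + 1)  # counts[w + 1] = #assignments with W+ = w
  counts[1] <- 1
  for (ri in r) {
    shifted <- c(rep(0, ri), counts[seq_len(tot + 1 - ri)])
    counts <- counts + shifted
  }
  counts / 2^length(r)
}

# Exact two-sided p: probability of a W+ at least as far from its mean as
# the observed one, under sign-flip enumeration.
exact_wilcoxon_p <- function(d) {
  probs <- wplus_null_distribution(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  w_all <- seq_along(probs) - 1
  sum(probs[abs(w_all - mu) >= abs(w_obs - mu) - 1e-9])
}

# AUC as the Mann-Whitney statistic by brute-force pair enumeration,
# ties counted one half.
auc_pair_enumeration <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Quadratic-weighted kappa computed independently with explicit loops
# over the confusion matrix.
qwk_direct <- function(a, b, cats) {
  k <- length(cats)
  n <- length(a)
  ia <- match(a, cats)
  ib <- match(b, cats)
  num_o <- 0
  for (t in seq_len(n)) {
    num_o <- num_o + (1 - ((ia[t] - ib[t]) / (k - 1))^2)
  }
  p_o <- num_o / n
  p_e <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      p_e <- p_e + mean(ia == i) * mean(ib == j) *
        (1 - ((i - j) / (k - 1))^2)
    }
  }
  (p_o - p_e) / (1 - p_e)
}

# small valid observation table built in code
make_obs <- function(n_patients = 4, conscious = c(TRUE, TRUE, FALSE, FALSE)) {
  rows <- list()
  for (p in seq_len(n_patients)) {
    for (ph in c("before", "during", "after")) {
      lev <- switch(ph, before = 0L, during = 1L, after = 0L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = sprintf("P%02d", p), session_day = 1L, phase = ph,
        conscious = conscious[p],
        vas = if (conscious[p]) 2L + 5L * lev else NA_integer_,
        bps_facial = 1L + 2L * lev, bps_upper_limb = 1L + lev,
        bps_ventilator = 1L + lev,
        cpot_facial = 0L + 2L * lev, cpot_body = 0L + lev,
        cpot_tension = 0L + lev, cpot_ventilator = 0L + lev)
    }
  }
  dplyr::bind_rows(rows)
}
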