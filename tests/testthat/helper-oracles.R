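# Independent brute-force oracles and small generators used across the suite.

# Random labelled cohort; about half the draws use coarsely rounded scores so
# tie handling is exercised.
random_cohort <- function(n, seed, tie_heavy = NULL) {
  set.seed(seed)
  if (is.null(tie_heavy)) tie_heavy <- runif(1) < 0.5
  n_pos <- sample(seq_len(n - 1L), 1L)
  label <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  score <- runif(n)
  if (tie_heavy) score <- round(score, 1L)
  scored_cohort(paste0("L", seq_len(n)), score, label)
}

# Mann-Whitney pairwise oracle: P(random melanoma outscores random benign),
# ties counting one half. Quadratic; independent of the curve construction.
oracle_auc <- function(cohort) {
  sp <- cohort$score[cohort$label == "malignant"]
  sn <- cohort$score[cohort$label == "benign"]
  mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
}

# Rank-cut enumeration oracle for average precision: every distinct score is
# a cut; counts taken by direct comparison, not by sorting/cumsum.
oracle_ap <- function(cohort) {
  y <- as.integer(cohort$label == "malignant")
  s <- cohort$score
  np <- sum(y)
  ap <- 0
  r_prev <- 0
  for (t in sort(unique(s), decreasing = TRUE)) {
    tp <- sum(y == 1L & s >= t)
    fp <- sum(y == 0L & s >= t)
    r <- tp / np
    ap <- ap + (r - r_prev) * (tp / (tp + fp))
    r_prev <- r
  }
  ap
}

# Exhaustive pair-count Kendall tau-b, written as an explicit double loop.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- sign(x[i] - x[j])
      b <- sign(y[i] - y[j])
      if (a == 0) tx <- tx + 1L
      if (b == 0) ty <- ty + 1L
      if (a * b > 0) C <- C + 1L
      if (a * b < 0) D <- D + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Gaussian feature cloud for sweep / CV tests.
small_features <- function(n, seed, d = 2L, sep = 1) {
  simulate_feature_table(n = n, n_pos = max(3L, round(n / 3)),
                         mu0 = rep(0, d), mu1 = rep(sep, d),
                         sigma0 = diag(d), sigma1 = diag(d) * 1.3,
                         seed = seed)
}

# Distinct operating points of a curve as a canonical sorted matrix.
point_set <- function(curve) {
  m <- unique(round(cbind(curve$fpr, curve$tpr), 12))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

# Perfectly separated toy cohort.
perfect_cohort <- function(n_pos = 3L, n_neg = 5L) {
  scored_cohort(paste0("P", seq_len(n_pos + n_neg)),
                c(seq(0.9, 0.7, length.out = n_pos),
                  seq(0.3, 0.1, length.out = n_neg)),
                c(rep(1L, n_pos), rep(0L, n_neg)))
}
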