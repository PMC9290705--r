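# Independent brute-force oracles the unit tests compare the package
# implementations against. These deliberately avoid the code paths they
# check.

# Spearman rho via explicit average ranks and the Pearson formula on ranks
# (handles ties the same way as the average-rank convention).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# AUC by explicit enumeration of all positive/negative pairs.
oracle_auc_pairs <- function(pos, neg) {
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# AUC by trapezoidal integration of the empirical ROC curve.
oracle_auc_trapezoid <- function(pos, neg) {
  cuts <- sort(unique(c(pos, neg, -Inf, Inf)))
  fpr <- vapply(cuts, function(c) mean(neg > c), numeric(1))
  tpr <- vapply(cuts, function(c) mean(pos > c), numeric(1))
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Exhaustive Youden scan over every midpoint cutoff.
oracle_youden <- function(pos, neg) {
  s <- sort(unique(c(pos, neg)))
  cuts <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best_j <- -Inf; best_cut <- NA
  for (c in cuts) {
    j <- mean(pos > c) + mean(neg <= c) - 1
    if (j > best_j + 1e-12) { best_j <- j; best_cut <- c }
  }
  list(cutoff = best_cut, j = best_j)
}

# Closed-form mean of a Rician variate (Laguerre-polynomial form), used to
# check the noise sampler's limits.
oracle_rician_mean <- function(s, sigma) {
  x <- -s^2 / (2 * sigma^2)
  l_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * l_half
}

# Small reduced cohort design used by pipeline-level tests (2 timepoints,
# 3 PBDL mice each, 2 sham, tiny grids) so suites stay fast.
tiny_design <- function(seed = 42, n_sham = 2, ...) {
  cohort_design(timepoints = c(2, 8), n_pbdl_per_timepoint = 3,
                n_sham = n_sham, grid_shape = c(6, 6, 1), seed = seed, ...)
}
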