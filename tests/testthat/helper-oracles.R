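# Independent oracles used across the test files. Each one recomputes the
# quantity from its definition along a different computational path than the
# package implementation.

# Brute-force Mann-Whitney AUC: enumerate all pairs, 0.5 credit per tie.
oracle_auc <- function(x, y) {
  mean(outer(y, x, ">") + 0.5 * outer(y, x, "=="))
}

# Dense-grid OVL oracle: evaluate both Gaussian-kernel densities exactly on a
# shared dense grid spanning both supports and integrate the pointwise
# minimum with the trapezoid rule.
oracle_ovl <- function(a, b, n = 10001L) {
  ha <- bandwidth_adaptive(a)
  hb <- bandwidth_adaptive(b)
  lo <- min(min(a) - 3 * ha, min(b) - 3 * hb)
  hi <- max(max(a) + 3 * ha, max(b) + 3 * hb)
  g <- seq(lo, hi, length.out = n)
  fa <- vapply(g, function(t) mean(stats::dnorm(t, a, ha)), 0)
  fb <- vapply(g, function(t) mean(stats::dnorm(t, b, hb)), 0)
  m <- pmin(fa, fb)
  sum((m[-1L] + m[-n]) / 2) * (g[2L] - g[1L])
}

# ABCR oracle: rebuild the empirical ROC vertices from the definition of
# sensitivity / 1-specificity at every distinct pooled value, then compute
# each partial area by fine numeric integration of the piecewise-linear
# curve (2001 evaluation points per partition interval) instead of exact
# cumulative trapezoids.
oracle_abcr <- function(x, y) {
  thr <- sort(unique(c(x, y)), decreasing = TRUE)
  fpr <- c(0, vapply(thr, function(t) mean(x > t), 0), 1)
  tpr <- c(0, vapply(thr, function(t) mean(y > t), 0), 1)
  m0 <- length(thr)
  height <- function(q) {
    lo <- max(which(fpr <= q))
    hi <- which(fpr >= q)[1L]
    if (fpr[lo] == fpr[hi]) return(mean(tpr[fpr == q]))
    tpr[lo] + (tpr[hi] - tpr[lo]) * (q - fpr[lo]) / (fpr[hi] - fpr[lo])
  }
  breaks <- seq(0, 1, length.out = m0 + 1L)
  total <- 0
  for (k in seq_len(m0)) {
    qs <- seq(breaks[k], breaks[k + 1L], length.out = 2001L)
    hs <- vapply(qs, height, 0)
    auc_k <- sum((hs[-1L] + hs[-length(hs)]) / 2) * (qs[2L] - qs[1L])
    total <- total + abs(auc_k - (2 * k - 1) / (2 * m0^2))
  }
  total
}

# Sample skewness (population moments).
oracle_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}

# A hand-built grid density for toy tests.
grid_dens <- function(x, y) {
  structure(list(x = x, y = y, bw = 1), class = "kde_grid")
}
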