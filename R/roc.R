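# Nonparametric ROC machinery. The experimental group is always the positive
# class and the classification rule (value > threshold => positive) is never
# auto-flipped: an AUC near 1 means up-regulation, near 0 down-regulation, and
# a "not proper" curve that crosses the diagonal is itself informative, since
# equal-mean genes with bimodal or unequal-variance distributions produce it.

#' Mann-Whitney estimate of the area under the ROC curve
#'
#' Estimates \eqn{AUC = P(Y > X) + P(Y = X)/2} by the Mann-Whitney
#' U-statistic, where `x` is the control group and `y` the experimental group.
#'
#' @param x control-group values.
#' @param y experimental-group values.
#' @return a value in `[0, 1]`.
#' @examples
#' auc_mw(c(1, 2, 3), c(2, 3, 4))  # 7/9
#' @export
auc_mw <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n0 <- length(x); n1 <- length(y)
  if (n0 == 0L || n1 == 0L) stop("empty sample", call. = FALSE)
  r <- rank(c(x, y))                       # midranks give the 0.5 tie credit
  (sum(r[(n0 + 1L):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC curve of the rule "positive if value > threshold",
#' evaluated at every distinct pooled value plus the endpoints (0,0) and
#' (1,1). Its trapezoidal area equals [auc_mw()] exactly (Bamber's identity).
#'
#' @inheritParams auc_mw
#' @return an object of class `"roc_curve"`: list with non-decreasing `fpr`
#'   and `tpr` in `[0,1]`.
#' @export
empirical_roc <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  thr <- sort(unique(c(x, y)), decreasing = TRUE)
  fpr <- c(0, vapply(thr, function(t) mean(x > t), 0), 1)
  tpr <- c(0, vapply(thr, function(t) mean(y > t), 0), 1)
  structure(list(fpr = fpr, tpr = tpr), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d points, trapezoidal AUC = %.4f\n",
              length(x$fpr), roc_trapezoid_area(x)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

roc_trapezoid_area <- function(roc) {
  sum(0.5 * (roc$tpr[-1L] + roc$tpr[-length(roc$tpr)]) * diff(roc$fpr))
}

# Area under the piecewise-linear ROC curve from fpr = 0 up to fpr = q.
# Vertical jumps (repeated fpr) contribute zero width, so the cumulative
# area at a jump abscissa is well defined.
roc_cum_area <- function(roc, q) {
  fx <- roc$fpr; fy <- roc$tpr
  ca <- c(0, cumsum(0.5 * (fy[-1L] + fy[-length(fy)]) * diff(fx)))
  vapply(q, function(p) {
    i <- findInterval(p, fx)           # rightmost index with fx[i] <= p
    if (fx[i] == p || i == length(fx)) return(ca[i])
    yq <- fy[i] + (fy[i + 1L] - fy[i]) * (p - fx[i]) / (fx[i + 1L] - fx[i])
    ca[i] + 0.5 * (fy[i] + yq) * (p - fx[i])
  }, 0)
}

#' ABCR: area between the empirical ROC curve and the chance line
#'
#' Partitions the false-positive axis into \eqn{m_0} equal intervals, where
#' \eqn{m_0} is the number of distinct pooled values (ties are not counted
#' twice), and sums the absolute differences between the partial trapezoidal
#' areas of the empirical ROC curve and the matching partial areas
#' \eqn{A_k = (2k-1)/(2 m_0^2)} of the diagonal. ABCR is a distance between
#' the two expression distributions that remains large for "not proper"
#' (diagonal-crossing) curves whose plain AUC is close to 0.5.
#'
#' @inheritParams auc_mw
#' @return a nonnegative value.
#' @export
abcr <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m0 <- length(unique(c(x, y)))
  if (m0 < 2L) stop("need at least 2 distinct pooled values", call. = FALSE)
  roc <- empirical_roc(x, y)
  breaks <- seq(0, 1, length.out = m0 + 1L)
  cum <- roc_cum_area(roc, breaks)
  auc_k <- diff(cum)
  a_k <- (2 * seq_len(m0) - 1) / (2 * m0^2)
  sum(abs(auc_k - a_k))
}

#' TNRC: test statistic for not-proper ROC curves
#'
#' \eqn{TNRC = ABCR - |AUC - 0.5|}. For a curve that never crosses the
#' diagonal the absolute partial-area differences telescope and TNRC is zero;
#' large positive values flag sigmoidal, diagonal-crossing curves typical of
#' bimodal or unequal-variance genes with similar group means.
#'
#' @inheritParams auc_mw
#' @return a nonnegative value (up to floating-point error).
#' @export
tnrc <- function(x, y) {
  abcr(x, y) - abs(auc_mw(x, y) - 0.5)
}
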