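# Benchmark harness: score gene-ranking statistics against simulated ground
# truth with a method-performance ROC (genes are the classification units:
# truly differentially expressed genes are the positives, null genes the
# negatives).

#' Construct a method-score object
#'
#' @param method method name.
#' @param score named numeric vector (names = gene identifiers).
#' @param direction how the score is oriented before ranking: `"abs"` (high
#'   absolute value = differentially expressed), `"low"` (low value = DE, as
#'   for OVL) or `"fold_auc"` (an AUC-type score folded to `max(a, 1 - a)`).
#' @return an object of class `"method_score"`.
#' @export
method_score <- function(method, score, direction = c("abs", "low", "fold_auc")) {
  direction <- match.arg(direction)
  if (is.null(names(score))) stop("scores must be named by gene", call. = FALSE)
  structure(list(method = method, score = score, direction = direction),
            class = "method_score")
}

#' @export
print.method_score <- function(x, ...) {
  cat(sprintf("Method scores: %s (%d genes, direction = %s)\n",
              x$method, length(x$score), x$direction))
  invisible(x)
}

oriented_score <- function(ms) {
  switch(ms$direction,
         abs = abs(ms$score),
         low = -ms$score,
         fold_auc = pmax(ms$score, 1 - ms$score))
}

#' Built-in baseline ranking statistics
#'
#' Computes one per-gene score over a dataset:
#' \describe{
#'   \item{FC}{log fold change: difference of group means on the log scale.}
#'   \item{AD}{average difference of expression between the groups; on
#'     log-scale data this coincides with FC and is kept as a separate method
#'     name for report compatibility.}
#'   \item{WELCH_T}{Welch two-sample t statistic (unequal variances). Genes
#'     where both groups are constant get an undefined (`NA`) score.}
#'   \item{OVL}{overlapping coefficient ([ovl()]); low values indicate
#'     differential expression.}
#'   \item{AUC_STAT}{the Mann-Whitney AUC itself ([auc_mw()]); folded around
#'     0.5 when ranked.}
#' }
#'
#' @param data an [expression_dataset()].
#' @param method one of `"FC"`, `"AD"`, `"WELCH_T"`, `"OVL"`, `"AUC_STAT"`.
#' @param ... kernel density settings forwarded to [ovl()] for
#'   `method = "OVL"`.
#' @return a [method_score()] object.
#' @export
baseline_scores <- function(data, method = c("FC", "AD", "WELCH_T", "OVL", "AUC_STAT"),
                            ...) {
  method <- match.arg(method)
  stopifnot(inherits(data, "expression_dataset"))
  p <- length(data$genes)
  score <- rep(NA_real_, p)
  for (i in seq_len(p)) {
    xi <- data$control[i, ]; xi <- xi[!is.na(xi)]
    yi <- data$experimental[i, ]; yi <- yi[!is.na(yi)]
    score[i] <- switch(method,
      FC = mean(yi) - mean(xi),
      AD = mean(yi) - mean(xi),
      WELCH_T = {
        se2 <- stats::var(xi) / length(xi) + stats::var(yi) / length(yi)
        if (se2 == 0) NA_real_ else (mean(yi) - mean(xi)) / sqrt(se2)
      },
      OVL = tryCatch(ovl(xi, yi, ...), error = function(e) NA_real_),
      AUC_STAT = auc_mw(xi, yi))
  }
  names(score) <- data$genes
  method_score(method, score,
               direction = switch(method, OVL = "low", AUC_STAT = "fold_auc", "abs"))
}

#' Performance AUC of a ranking statistic against simulation truth
#'
#' Orients the scores so that high values indicate differential expression
#' (see [method_score()]), then computes the Mann-Whitney AUC separating the
#' genes whose true class is in `positive_classes` from the null genes. Genes
#' of other classes are excluded from the evaluation set.
#'
#' @param scores a [method_score()] object covering every gene in `truth`.
#' @param truth the `truth` data frame of [simulate_microarray()] (columns
#'   `gene`, `class`).
#' @param positive_classes character vector of true classes counted as
#'   positives; default `c("up", "down", "special")`.
#' @return the performance AUC in `[0, 1]`.
#' @export
performance_auc <- function(scores, truth,
                            positive_classes = c("up", "down", "special")) {
  stopifnot(inherits(scores, "method_score"))
  if (!all(truth$gene %in% names(scores$score))) {
    stop("scores missing for some genes in truth", call. = FALSE)
  }
  s <- scores$score[truth$gene]
  oriented <- switch(scores$direction,
                     abs = abs(s), low = -s, fold_auc = pmax(s, 1 - s))
  pos <- truth$class %in% positive_classes
  neg <- truth$class == "null"
  keep <- (pos | neg) & !is.na(oriented)
  auc_mw(oriented[neg & keep], oriented[pos & keep])
}

#' Benchmark several ranking statistics on one simulated dataset
#'
#' @param sim result of [simulate_microarray()].
#' @param methods built-in methods to score (see [baseline_scores()]).
#' @param extra_scores optional list of [method_score()] objects (e.g. from
#'   [read_score_file()]).
#' @param ... forwarded to [baseline_scores()].
#' @return a data frame with columns `method`, `scenario`
#'   (`all_de` = up + down + special vs null; `special_only` = special vs
#'   null, up/down genes excluded) and `auc`.
#' @export
benchmark_methods <- function(sim, methods = c("OVL", "FC", "AD", "WELCH_T", "AUC_STAT"),
                              extra_scores = list(), ...) {
  all_scores <- c(lapply(methods, function(m) baseline_scores(sim$data, m, ...)),
                  extra_scores)
  rows <- lapply(all_scores, function(ms) {
    data.frame(method = ms$method,
               scenario = c("all_de", "special_only"),
               auc = c(performance_auc(ms, sim$truth),
                       performance_auc(ms, sim$truth, "special")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "negatives") <- "null genes only; up/down excluded from special_only"
  out
}
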