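# Plain-text I/O: expression matrices (TSV/CSV, genes in rows, first column =
# gene identifier), group assignments, result tables and score files.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

parse_group_spec <- function(group_spec, samples) {
  if (is.character(group_spec) && length(group_spec) == 1L && file.exists(group_spec)) {
    tab <- utils::read.table(group_spec, header = TRUE, sep = detect_sep(group_spec),
                             stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(tab))) {
      stop("group file needs columns 'sample' and 'group'", call. = FALSE)
    }
    grp <- tolower(tab$group)
    if (!all(grp %in% c("control", "experimental"))) {
      stop("group values must be 'control' or 'experimental'", call. = FALSE)
    }
    group_spec <- list(control = tab$sample[grp == "control"],
                       experimental = tab$sample[grp == "experimental"])
  }
  if (!is.list(group_spec) ||
      !all(c("control", "experimental") %in% names(group_spec))) {
    stop("group_spec must be a list with 'control' and 'experimental' sample names, or a file path",
         call. = FALSE)
  }
  missing_cols <- setdiff(unlist(group_spec), samples)
  if (length(missing_cols)) {
    stop("unknown sample columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  group_spec
}

#' Read a two-group expression matrix from TSV/CSV
#'
#' The file must have a header row; the first column holds unique gene
#' identifiers and the remaining columns one array each. Empty fields and
#' `NA` are treated as missing. The delimiter (tab or comma) is detected from
#' the header line unless `sep` is given.
#'
#' @param path file path.
#' @param group_spec either a list
#'   `list(control = <sample names>, experimental = <sample names>)` or the
#'   path of a two-column TSV/CSV with columns `sample` and `group`
#'   (values `control`/`experimental`).
#' @param sep optional delimiter override.
#' @return an [expression_dataset()].
#' @export
read_expression_matrix <- function(path, group_spec, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 3L) stop("expected a gene column plus at least 2 arrays", call. = FALSE)
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicated gene identifiers in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!apply(tab[, -1L, drop = FALSE], 2, is.numeric))
    stop("non-numeric expression column(s): ",
         paste(colnames(mat)[bad], collapse = ", "), call. = FALSE)
  }
  spec <- parse_group_spec(group_spec, colnames(mat))
  expression_dataset(mat[, spec$control, drop = FALSE],
                     mat[, spec$experimental, drop = FALSE],
                     genes = genes)
}

#' Write a per-gene results table
#'
#' Writes `gene`, `OVL`, `AUC`, `modality_group` and `label`, stable-sorted by
#' label and ascending OVL within label, with 4 decimal places.
#'
#' @param stats the `stats` data frame of an [arrow_fit()] object (or the
#'   object itself).
#' @param path output TSV path.
#' @return invisibly, the written data frame.
#' @export
write_gene_stats <- function(stats, path) {
  if (inherits(stats, "arrow_fit")) stats <- stats$stats
  out <- stats[order(stats$label, stats$ovl), , drop = FALSE]
  res <- data.frame(gene = out$gene,
                    OVL = sprintf("%.4f", out$ovl),
                    AUC = sprintf("%.4f", out$auc),
                    modality_group = ifelse(is.na(out$modality), "", out$modality),
                    label = as.character(out$label),
                    stringsAsFactors = FALSE)
  res$OVL[is.na(out$ovl)] <- "NA"
  res$AUC[is.na(out$auc)] <- "NA"
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' Read an external per-gene score file
#'
#' Two-column TSV/CSV (`gene_id`, `score`), used to benchmark ranking
#' statistics computed outside the package (e.g. moderated t variants).
#'
#' @param path file path.
#' @param method name to attach to the scores.
#' @param direction `"abs"` (rank by absolute value, the default for
#'   mean-difference style statistics), `"low"` (low score = differentially
#'   expressed, as for OVL) or `"fold_auc"` (AUC-type score folded around
#'   0.5).
#' @return a `"method_score"` object (see [baseline_scores()]).
#' @export
read_score_file <- function(path, method = basename(path),
                            direction = c("abs", "low", "fold_auc")) {
  direction <- match.arg(direction)
  tab <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("score file needs columns gene_id and score", call. = FALSE)
  score <- as.numeric(tab[[2L]])
  names(score) <- as.character(tab[[1L]])
  method_score(method, score, direction)
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Fills each missing entry with the average of that array's values over the
#' `k` genes nearest to the target gene (Euclidean distance on the arrays both
#' genes observe), considering only neighbour genes with the entry observed.
#' Provided as a preprocessing hook for datasets distributed with missing
#' values; rows that cannot be imputed fall back to the gene mean.
#'
#' @param mat numeric matrix, genes x arrays, with `NA` for missing entries.
#' @param k number of neighbours (default 10).
#' @return the matrix with missing entries filled.
#' @export
impute_knn <- function(mat, k = 10L) {
  mat <- as.matrix(mat)
  miss_rows <- which(rowSums(is.na(mat)) > 0L)
  if (!length(miss_rows)) return(mat)
  complete <- mat[rowSums(is.na(mat)) == 0L, , drop = FALSE]
  out <- mat
  for (i in miss_rows) {
    target <- mat[i, ]
    obs <- !is.na(target)
    if (!any(obs) || nrow(complete) == 0L) {
      out[i, !obs] <- mean(target, na.rm = TRUE)
      next
    }
    d2 <- colSums((t(complete[, obs, drop = FALSE]) - target[obs])^2)
    nb <- complete[order(d2)[seq_len(min(k, nrow(complete)))], , drop = FALSE]
    fill <- colMeans(nb[, !obs, drop = FALSE])
    fill[is.na(fill)] <- mean(target, na.rm = TRUE)
    out[i, !obs] <- fill
  }
  out
}

#' Reproduce the lymphoma benchmark analysis
#'
#' Convenience wrapper for the published two-group lymphoma comparison
#' (4026 genes; 14 normal B-cell arrays vs 20 lymphoma arrays): reads the
#' matrix, KNN-imputes missing values (k = 10), fits the arrow screen at the
#' lymphoma thresholds (OVL < 0.5; AUC >= 0.9 / <= 0.1 / (0.4, 0.6)) and
#' returns the fit. The dataset is not distributed with the package; supply
#' your own copy.
#'
#' @param path expression matrix TSV (first column gene IDs).
#' @param group_spec see [read_expression_matrix()].
#' @param k neighbours for imputation.
#' @return an [arrow_fit()] object.
#' @export
reproduce_lymphoma <- function(path, group_spec, k = 10L) {
  data <- read_expression_matrix(path, group_spec)
  mat <- impute_knn(cbind(data$control, data$experimental), k = k)
  nc <- ncol(data$control)
  data <- expression_dataset(mat[, seq_len(nc), drop = FALSE],
                             mat[, -seq_len(nc), drop = FALSE],
                             genes = data$genes)
  arrow_fit(data, thresholds = arrow_thresholds(preset = "lymphoma"))
}
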