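# Two-group expression container. Plain matrices with genes in rows; the
# control and experimental arrays are kept as separate matrices sharing the
# gene order.

#' Two-group expression dataset
#'
#' Bundles a control and an experimental log-scale expression matrix with a
#' shared set of gene identifiers.
#'
#' @param control numeric matrix, genes x control arrays (>= 2 columns).
#' @param experimental numeric matrix, genes x experimental arrays (>= 2
#'   columns), same number of rows as `control`.
#' @param genes character vector of unique gene identifiers, one per row;
#'   defaults to the rownames of `control`.
#' @return an object of class `"expression_dataset"`.
#' @export
expression_dataset <- function(control, experimental, genes = rownames(control)) {
  control <- as.matrix(control)
  experimental <- as.matrix(experimental)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(control)))
  genes <- as.character(genes)
  if (nrow(control) != nrow(experimental)) {
    stop("control and experimental matrices must have the same genes (rows)",
         call. = FALSE)
  }
  if (length(genes) != nrow(control)) {
    stop("gene identifiers must match the number of rows", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicated gene identifiers: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (ncol(control) < 2L || ncol(experimental) < 2L) {
    stop("each group needs at least 2 arrays", call. = FALSE)
  }
  bad <- c(control, experimental)
  if (any(!is.na(bad) & !is.finite(bad))) {
    stop("expression values must be finite or NA", call. = FALSE)
  }
  rownames(control) <- rownames(experimental) <- genes
  structure(list(genes = genes, control = control, experimental = experimental),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes, %d control + %d experimental arrays\n",
              length(x$genes), ncol(x$control), ncol(x$experimental)))
  n_na <- sum(is.na(x$control)) + sum(is.na(x$experimental))
  if (n_na > 0) cat(sprintf("  %d missing values\n", n_na))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) {
  c(length(x$genes), ncol(x$control) + ncol(x$experimental))
}
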