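# The arrow plot screen: per-gene OVL and AUC, two-criterion classification
# into up-regulated / down-regulated / special genes, and the plot itself.

#' Selection thresholds for the arrow plot
#'
#' @param auc_up minimum AUC for up-regulation (gene selected when
#'   `auc >= auc_up` and `ovl < ovl_max`); default 0.9.
#' @param auc_down maximum AUC for down-regulation (`auc <= auc_down`);
#'   default 0.1.
#' @param auc_special_low,auc_special_high open AUC band for special-gene
#'   candidates (`auc_special_low < auc < auc_special_high`); defaults 0.4 and
#'   0.6.
#' @param ovl_max strict OVL ceiling applied to every category; default 0.5.
#' @param preset optional named preset: `"lymphoma"` (ovl_max 0.5, the default
#'   thresholds) or `"simulation"` (ovl_max 0.3, as used for simulated data
#'   where null genes with strongly unequal group variances would otherwise
#'   leak into the candidate band). Explicit arguments override the preset.
#' @return an object of class `"arrow_thresholds"`.
#' @export
arrow_thresholds <- function(auc_up = 0.9, auc_down = 0.1,
                             auc_special_low = 0.4, auc_special_high = 0.6,
                             ovl_max = 0.5, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("lymphoma", "simulation"))
    if (preset == "simulation" && missing(ovl_max)) ovl_max <- 0.3
  }
  th <- list(auc_up = auc_up, auc_down = auc_down,
             auc_special_low = auc_special_low,
             auc_special_high = auc_special_high, ovl_max = ovl_max)
  if (!(0 <= th$auc_down && th$auc_down < th$auc_special_low &&
        th$auc_special_low < th$auc_special_high &&
        th$auc_special_high < th$auc_up && th$auc_up <= 1)) {
    stop("need 0 <= auc_down < auc_special_low < auc_special_high < auc_up <= 1",
         call. = FALSE)
  }
  if (!(th$ovl_max > 0 && th$ovl_max <= 1)) {
    stop("ovl_max must be in (0, 1]", call. = FALSE)
  }
  structure(th, class = "arrow_thresholds")
}

#' @export
print.arrow_thresholds <- function(x, ...) {
  cat(sprintf(
    "Arrow plot thresholds: OVL < %g; AUC >= %g (up), <= %g (down), (%g, %g) (special)\n",
    x$ovl_max, x$auc_up, x$auc_down, x$auc_special_low, x$auc_special_high))
  invisible(x)
}

#' Per-gene OVL and AUC statistics
#'
#' Computes, for every gene, the overlapping coefficient between the two
#' group densities and the Mann-Whitney AUC with the experimental group as
#' the positive class. Genes whose statistics cannot be computed (fewer than
#' two non-missing values in a group, or a constant group) are reported with
#' `NA` statistics and the error message rather than aborting the run.
#'
#' @param data an [expression_dataset()].
#' @param n_grid,cut,bw_rule kernel density settings, see [kde_grid()].
#' @return a data frame with columns `gene`, `ovl`, `auc`, `error`
#'   (`NA_character_` when the gene computed cleanly).
#' @export
compute_gene_stats <- function(data, n_grid = 512L, cut = 3,
                               bw_rule = c("adaptive", "sd")) {
  stopifnot(inherits(data, "expression_dataset"))
  bw_rule <- match.arg(bw_rule)
  p <- length(data$genes)
  ovl_v <- auc_v <- rep(NA_real_, p)
  err_v <- rep(NA_character_, p)
  for (i in seq_len(p)) {
    xi <- data$control[i, ]; xi <- xi[!is.na(xi)]
    yi <- data$experimental[i, ]; yi <- yi[!is.na(yi)]
    res <- tryCatch({
      list(ovl = ovl(xi, yi, n_grid = n_grid, cut = cut, bw_rule = bw_rule),
           auc = auc_mw(xi, yi))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      err_v[i] <- conditionMessage(res)
    } else {
      ovl_v[i] <- res$ovl
      auc_v[i] <- res$auc
    }
  }
  data.frame(gene = data$genes, ovl = ovl_v, auc = auc_v, error = err_v,
             stringsAsFactors = FALSE)
}

#' Classify genes from their OVL and AUC statistics
#'
#' Applies the two-criterion rule: `UP` when `auc >= auc_up` and
#' `ovl < ovl_max`; `DOWN` when `auc <= auc_down` and `ovl < ovl_max`;
#' special-gene candidates when `ovl < ovl_max` and
#' `auc_special_low < auc < auc_special_high`. Candidates are kept as
#' `SPECIAL` only when the kernel density of at least one group is bimodal or
#' multimodal ([modality_label()] in `C`, `E` or `B`); unimodal candidates --
#' typically null genes with strongly unequal group variances -- revert to
#' `NS`. Genes with failed statistics get the label `UNDETERMINED`.
#'
#' @param stats data frame from [compute_gene_stats()].
#' @param data the [expression_dataset()] the statistics came from (needed for
#'   the bimodality step).
#' @param thresholds an [arrow_thresholds()] object.
#' @param n_grid,cut,bw_rule kernel density settings for the bimodality step.
#' @return `stats` with added columns `modality` (`C`/`E`/`B`/`U`, `NA` for
#'   genes where it was not evaluated) and `label` (factor with levels `UP`,
#'   `DOWN`, `SPECIAL`, `NS`, `UNDETERMINED`).
#' @export
select_genes <- function(stats, data, thresholds = arrow_thresholds(),
                         n_grid = 512L, cut = 3, bw_rule = c("adaptive", "sd")) {
  stopifnot(inherits(thresholds, "arrow_thresholds"))
  bw_rule <- match.arg(bw_rule)
  th <- thresholds
  ok <- !is.na(stats$ovl) & !is.na(stats$auc)
  low_ovl <- ok & stats$ovl < th$ovl_max
  up <- low_ovl & stats$auc >= th$auc_up
  down <- low_ovl & stats$auc <= th$auc_down
  cand <- low_ovl & stats$auc > th$auc_special_low & stats$auc < th$auc_special_high

  modality <- rep(NA_character_, nrow(stats))
  idx <- match(stats$gene, data$genes)
  for (i in which(cand)) {
    j <- idx[i]
    xi <- data$control[j, ]; xi <- xi[!is.na(xi)]
    yi <- data$experimental[j, ]; yi <- yi[!is.na(yi)]
    modality[i] <- tryCatch(
      modality_label(xi, yi, n_grid = n_grid, cut = cut, bw_rule = bw_rule),
      error = function(e) NA_character_)
  }
  special <- cand & !is.na(modality) & modality %in% c("C", "E", "B")

  label <- rep("NS", nrow(stats))
  label[up] <- "UP"
  label[down] <- "DOWN"
  label[special] <- "SPECIAL"
  label[!ok] <- "UNDETERMINED"
  stats$modality <- modality
  stats$candidate <- cand
  stats$label <- factor(label, levels = c("UP", "DOWN", "SPECIAL", "NS", "UNDETERMINED"))
  stats
}

#' Fit the arrow plot screen to a two-group expression dataset
#'
#' The main entry point: computes per-gene OVL and AUC, classifies every gene
#' as up-regulated, down-regulated, special (similar means but bimodal or
#' multimodal in at least one group) or not selected, and returns an object
#' that prints, summarises and plots (the arrow plot: OVL on the x-axis, AUC
#' on the y-axis).
#'
#' @param data an [expression_dataset()], or a genes x arrays matrix if
#'   `groups` is supplied.
#' @param groups when `data` is a matrix: a vector (length = number of
#'   columns) with two levels; the first level (of the factor, or
#'   alphabetically) is the control group unless `control` names it.
#' @param control optional value of `groups` identifying the control group.
#' @param thresholds an [arrow_thresholds()] object.
#' @param n_grid,cut,bw_rule kernel density settings, see [kde_grid()] and
#'   [bandwidth_adaptive()].
#' @return an object of class `"arrow_fit"` with components `stats` (per-gene
#'   data frame with `gene`, `ovl`, `auc`, `modality`, `label`), `thresholds`,
#'   `n` (arrays per group) and `call`.
#' @examples
#' sim <- simulate_microarray(sim_config(p_total = 60, n_up = 10, n_down = 10,
#'                                       n_special = 5, seed = 1))
#' fit <- arrow_fit(sim$data, thresholds = arrow_thresholds(preset = "simulation"))
#' summary(fit)
#' @export
arrow_fit <- function(data, groups = NULL, control = NULL,
                      thresholds = arrow_thresholds(),
                      n_grid = 512L, cut = 3, bw_rule = c("adaptive", "sd")) {
  bw_rule <- match.arg(bw_rule)
  if (!inherits(data, "expression_dataset")) {
    data <- as.matrix(data)
    if (is.null(groups)) stop("supply `groups` when `data` is a matrix", call. = FALSE)
    if (length(groups) != ncol(data)) {
      stop("`groups` must have one entry per column of `data`", call. = FALSE)
    }
    groups <- as.character(groups)
    lev <- unique(groups)
    if (length(lev) != 2L) stop("`groups` must have exactly 2 levels", call. = FALSE)
    if (is.null(control)) control <- sort(lev)[1L]
    if (!control %in% lev) stop("`control` is not a level of `groups`", call. = FALSE)
    data <- expression_dataset(data[, groups == control, drop = FALSE],
                               data[, groups != control, drop = FALSE],
                               genes = rownames(data))
  }
  stats <- compute_gene_stats(data, n_grid = n_grid, cut = cut, bw_rule = bw_rule)
  stats <- select_genes(stats, data, thresholds, n_grid = n_grid, cut = cut,
                        bw_rule = bw_rule)
  structure(list(stats = stats, thresholds = thresholds,
                 n = c(control = ncol(data$control),
                       experimental = ncol(data$experimental)),
                 call = match.call()),
            class = "arrow_fit")
}

#' @export
print.arrow_fit <- function(x, ...) {
  counts <- table(x$stats$label)
  cat("Arrow plot gene selection\n")
  print(x$thresholds)
  cat(sprintf("%d genes, %d + %d arrays: %d up, %d down, %d special, %d not selected",
              nrow(x$stats), x$n[["control"]], x$n[["experimental"]],
              counts[["UP"]], counts[["DOWN"]], counts[["SPECIAL"]], counts[["NS"]]))
  if (counts[["UNDETERMINED"]] > 0) {
    cat(sprintf(", %d undetermined", counts[["UNDETERMINED"]]))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.arrow_fit <- function(object, ...) {
  s <- object$stats
  sel <- s[s$label %in% c("UP", "DOWN", "SPECIAL"), , drop = FALSE]
  sel <- sel[order(sel$label, sel$ovl), , drop = FALSE]
  out <- list(counts = table(s$label), selected = sel,
              modality = table(s$modality[s$label == "SPECIAL"]),
              thresholds = object$thresholds)
  class(out) <- "summary.arrow_fit"
  out
}

#' @export
print.summary.arrow_fit <- function(x, ...) {
  print(x$thresholds)
  cat("Label counts:\n"); print(x$counts)
  if (length(x$modality)) {
    cat("Special genes by bimodal group (C = control, E = experimental, B = both):\n")
    print(x$modality)
  }
  cat(sprintf("%d selected genes (head, ascending OVL within label):\n",
              nrow(x$selected)))
  print(utils::head(x$selected[, c("gene", "ovl", "auc", "modality", "label")], 10),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.arrow_fit <- function(x, ...) x$stats

#' @export
coef.arrow_fit <- function(object, ...) {
  m <- as.matrix(object$stats[, c("ovl", "auc")])
  rownames(m) <- object$stats$gene
  m
}

arrow_palette <- c(UP = "red", DOWN = "blue", NS = "grey70",
                   UNDETERMINED = "grey40",
                   SPECIAL_C = "cyan3", SPECIAL_E = "orange", SPECIAL_B = "green3")

point_colors <- function(stats) {
  col <- arrow_palette[as.character(stats$label)]
  sp <- !is.na(stats$label) & stats$label == "SPECIAL"
  col[sp] <- arrow_palette[paste0("SPECIAL_", stats$modality[sp])]
  col
}

#' Arrow plot
#'
#' Scatter of per-gene OVL (x-axis) against AUC (y-axis) with the selection
#' regions outlined. Up-regulated genes appear red near (low OVL, AUC -> 1),
#' down-regulated blue near (low OVL, AUC -> 0); special genes sit at AUC
#' around 0.5 and are coloured by the group showing bimodality: orange for
#' the experimental group, cyan for the control group, green for both.
#'
#' @param x an `"arrow_fit"` object.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the named vector of label counts shown in the legend.
#' @export
plot.arrow_fit <- function(x, main = "Arrow plot", ...) {
  s <- x$stats[!is.na(x$stats$ovl) & !is.na(x$stats$auc), , drop = FALSE]
  th <- x$thresholds
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "OVL", ylab = "AUC",
                 main = main, ...)
  if (nrow(s)) {
    graphics::points(s$ovl, s$auc, pch = 16, cex = 0.5, col = point_colors(s))
  }
  graphics::abline(v = th$ovl_max, lty = 2, col = "grey40")
  graphics::segments(0, c(th$auc_up, th$auc_down, th$auc_special_low, th$auc_special_high),
                     th$ovl_max, lty = 3, col = "grey40")
  counts <- c(UP = sum(s$label == "UP"), DOWN = sum(s$label == "DOWN"),
              `SPECIAL (E)` = sum(s$label == "SPECIAL" & s$modality == "E"),
              `SPECIAL (C)` = sum(s$label == "SPECIAL" & s$modality == "C"),
              `SPECIAL (B)` = sum(s$label == "SPECIAL" & s$modality == "B"),
              NS = sum(s$label == "NS"))
  graphics::legend("topright", bty = "n", pch = 16, cex = 0.8,
                   col = c(arrow_palette[c("UP", "DOWN")],
                           arrow_palette[c("SPECIAL_E", "SPECIAL_C", "SPECIAL_B")],
                           arrow_palette[["NS"]]),
                   legend = sprintf("%s: %d", names(counts), counts))
  invisible(counts)
}

#' Write an arrow plot to an image file
#'
#' @param fit an `"arrow_fit"` object.
#' @param path output file; `.png` or `.svg` decides the device.
#' @param width,height device size in pixels (png) or inches (svg).
#' @param ... passed to [plot.arrow_fit()].
#' @return invisibly, the label counts drawn in the legend.
#' @export
arrow_plot_file <- function(fit, path, width = 900, height = 700, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width / 100, height = height / 100)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height)
  } else {
    stop("unsupported image format: ", ext, " (use .png or .svg)", call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  counts <- plot(fit, ...)
  invisible(counts)
}
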