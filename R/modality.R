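# Bimodality / multimodality detection from the monotonicity pattern of the
# kernel density ordinates. No prominence threshold or extra smoothing is
# applied: the adaptive bandwidth is what suppresses spurious noise peaks.

#' Multimodality test on a grid density
#'
#' Labels each grid position as "rising" when its ordinate is less than or
#' equal to the next one. A unimodal density rises over one contiguous run of
#' positions and then falls, so the density is declared multimodal exactly
#' when the rising positions form more than one contiguous run. Flat plateaus
#' (equal consecutive ordinates) count as rising and never split a run by
#' themselves.
#'
#' @param density an object of class `"kde_grid"`, or any list with an
#'   ordinate component `y` of length >= 3.
#' @return `TRUE` if the density has more than one mode.
#' @examples
#' is_multimodal(list(y = c(1, 2, 3, 2, 1)))  # FALSE
#' is_multimodal(list(y = c(1, 2, 1, 2, 1)))  # TRUE
#' @export
is_multimodal <- function(density) {
  y <- density$y
  if (length(y) < 3L) stop("need at least 3 grid points", call. = FALSE)
  rising <- which(y[-length(y)] <= y[-1L])
  length(rising) > 1L && any(diff(rising) != 1L)
}

#' Group-wise modality label for a gene
#'
#' Estimates the kernel density of each group and reports where bimodality
#' (or multimodality) occurs: `"C"` control group only, `"E"` experimental
#' group only, `"B"` both, `"U"` neither (unimodal in both).
#'
#' @param x control-group values.
#' @param y experimental-group values.
#' @param n_grid,cut,bw_rule density settings, see [kde_grid()] and
#'   [bandwidth_adaptive()].
#' @return one of `"C"`, `"E"`, `"B"`, `"U"`.
#' @export
modality_label <- function(x, y, n_grid = 512L, cut = 3,
                           bw_rule = c("adaptive", "sd")) {
  bw_rule <- match.arg(bw_rule)
  mm_x <- is_multimodal(kde_grid(x, bandwidth_adaptive(x, rule = bw_rule),
                                 n_grid = n_grid, cut = cut))
  mm_y <- is_multimodal(kde_grid(y, bandwidth_adaptive(y, rule = bw_rule),
                                 n_grid = n_grid, cut = cut))
  if (mm_x && mm_y) "B" else if (mm_x) "C" else if (mm_y) "E" else "U"
}
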