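# Lognormal microarray simulator with ground truth. Expression values are
# drawn on the raw (lognormal) scale and log-transformed, so the stored
# values are normal on the log scale; mu and sigma below are the mean and
# standard deviation of the log-transformed values.

#' Simulation design for a two-group microarray experiment
#'
#' The default design: 10000 genes measured on 30 + 30 arrays, of which 9500
#' are not differentially expressed, 225 up-regulated, 225 down-regulated and
#' 50 "special" (similar group means, but one group drawn from a two-component
#' lognormal mixture, i.e. a hidden sample subclass).
#'
#' @param p_total total genes (default 10000).
#' @param n_per_group arrays per group (default 30).
#' @param n_up,n_down,n_special counts of up-regulated, down-regulated and
#'   special genes (defaults 225, 225, 50); the remainder are null genes.
#' @param null_mean_diff_range log-location difference (experimental minus
#'   control) for null genes; default `c(-0.9, 0.9)`.
#' @param null_var_diff_range difference between the two groups' log-scale
#'   variances for null genes, added to a base variance of 1 in a randomly
#'   chosen group; default `c(0, 12.25)`.
#' @param de_mean_diff_range magnitude of the log-location difference for
#'   up-regulated genes (negated for down-regulated); default `c(3.5, 13.5)`.
#' @param de_var_diff_range as `null_var_diff_range`, for up/down genes.
#' @param base_mu control-group log-location, default 3.5.
#' @param special_mu0 lower mixture component location for special genes
#'   (default 3.5).
#' @param special_mu1_range upper mixture component location range (default
#'   `c(7, 17)`).
#' @param special_sigma log-scale standard deviation of both mixture
#'   components and of the unimodal group of a special gene (default 1.2).
#' @param special_alpha mixing weight of the lower component (default 0.5);
#'   the unimodal group's location is `alpha * mu0 + (1 - alpha) * mu1`, so
#'   the two groups share their log-scale mean.
#' @param seed default root seed used by [simulate_microarray()] when none is
#'   given there.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(p_total = 10000L, n_per_group = 30L,
                       n_up = 225L, n_down = 225L, n_special = 50L,
                       null_mean_diff_range = c(-0.9, 0.9),
                       null_var_diff_range = c(0, 12.25),
                       de_mean_diff_range = c(3.5, 13.5),
                       de_var_diff_range = c(0, 12.25),
                       base_mu = 3.5,
                       special_mu0 = 3.5, special_mu1_range = c(7, 17),
                       special_sigma = 1.2, special_alpha = 0.5,
                       seed = 1L) {
  cfg <- list(p_total = as.integer(p_total), n_per_group = as.integer(n_per_group),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              n_special = as.integer(n_special),
              null_mean_diff_range = null_mean_diff_range,
              null_var_diff_range = null_var_diff_range,
              de_mean_diff_range = de_mean_diff_range,
              de_var_diff_range = de_var_diff_range,
              base_mu = base_mu,
              special_mu0 = special_mu0, special_mu1_range = special_mu1_range,
              special_sigma = special_sigma, special_alpha = special_alpha,
              seed = as.integer(seed))
  with(cfg, {
    if (n_up < 0 || n_down < 0 || n_special < 0 ||
        n_up + n_down + n_special > p_total) {
      stop("class counts must be nonnegative and sum to at most p_total",
           call. = FALSE)
    }
    if (n_per_group < 2L) stop("need at least 2 arrays per group", call. = FALSE)
    ranges <- list(null_mean_diff_range, null_var_diff_range,
                   de_mean_diff_range, de_var_diff_range, special_mu1_range)
    if (any(vapply(ranges, function(r) length(r) != 2L || r[1L] > r[2L], TRUE))) {
      stop("every range must be c(lower, upper) with lower <= upper", call. = FALSE)
    }
    if (special_alpha <= 0 || special_alpha >= 1) {
      stop("special_alpha must be in (0, 1)", call. = FALSE)
    }
    if (special_sigma <= 0) stop("special_sigma must be positive", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation design: %d genes (%d null, %d up, %d down, ",
                     "%d special), %d + %d arrays, seed %d\n"),
              x$p_total, x$p_total - x$n_up - x$n_down - x$n_special,
              x$n_up, x$n_down, x$n_special, x$n_per_group, x$n_per_group,
              x$seed))
  invisible(x)
}

runif1 <- function(range) stats::runif(1, range[1L], range[2L])

# log of a lognormal draw == normal draw; kept as the literal two-step form
# so the generating scale matches the stated design
rlnorm_log <- function(n, meanlog, sdlog) log(stats::rlnorm(n, meanlog, sdlog))

#' Simulate a two-group microarray dataset with ground truth
#'
#' Draws every gene independently from lognormal distributions and stores the
#' log-transformed values. Null genes: control location `base_mu`,
#' experimental location shifted by a uniform draw from
#' `null_mean_diff_range`; one randomly chosen group gets log-scale variance
#' 1, the other 1 plus a uniform draw from `null_var_diff_range`. Up- and
#' down-regulated genes: the same, with the location shift drawn from
#' `de_mean_diff_range` (negated for down). Special genes: one randomly
#' chosen group is a two-component mixture with locations `special_mu0` and a
#' uniform draw from `special_mu1_range` (both scales `special_sigma`); the
#' other group is unimodal lognormal with location
#' `alpha * mu0 + (1 - alpha) * mu1`, so the group means coincide on the log
#' scale while the shapes differ.
#'
#' Each gene uses its own random substream derived from the root seed, so
#' enlarging `p_total` leaves the values of the earlier genes unchanged.
#'
#' @param config a [sim_config()].
#' @param seed root seed; defaults to `config$seed`.
#' @return a list with components `data` (an [expression_dataset()]) and
#'   `truth` (data frame: `gene`, `class` in `null/up/down/special`,
#'   `mu_control`, `mu_experimental`, `var_control`, `var_experimental`,
#'   `mixture_group` (`control`/`experimental`/`NA`), `mu0`, `mu1`, `alpha`,
#'   `seed`).
#' @examples
#' sim <- simulate_microarray(sim_config(p_total = 100, n_up = 5, n_down = 5,
#'                                       n_special = 2, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_microarray <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$p_total
  n <- config$n_per_group
  classes <- rep("null", p)
  if (config$n_up > 0) classes[seq_len(config$n_up)] <- "up"
  if (config$n_down > 0) classes[config$n_up + seq_len(config$n_down)] <- "down"
  if (config$n_special > 0) {
    classes[config$n_up + config$n_down + seq_len(config$n_special)] <- "special"
  }

  # per-gene substreams: sample.int generates sequentially, so the first
  # genes keep their seeds when p_total grows
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, p)

  ctrl <- matrix(NA_real_, p, n)
  expr <- matrix(NA_real_, p, n)
  truth <- data.frame(gene = sprintf("gene%05d", seq_len(p)), class = classes,
                      mu_control = NA_real_, mu_experimental = NA_real_,
                      var_control = NA_real_, var_experimental = NA_real_,
                      mixture_group = NA_character_,
                      mu0 = NA_real_, mu1 = NA_real_, alpha = NA_real_,
                      seed = seed, stringsAsFactors = FALSE)

  for (i in seq_len(p)) {
    set.seed(sub_seeds[i])
    cl <- classes[i]
    if (cl == "special") {
      mu1 <- runif1(config$special_mu1_range)
      mu0 <- config$special_mu0
      a <- config$special_alpha
      sg <- config$special_sigma
      mix_in_experimental <- stats::runif(1) < 0.5
      comp <- stats::rbinom(n, 1L, 1 - a)      # 1 = upper component
      mix <- rlnorm_log(n, ifelse(comp == 1L, mu1, mu0), sg)
      uni <- rlnorm_log(n, a * mu0 + (1 - a) * mu1, sg)
      if (mix_in_experimental) {
        expr[i, ] <- mix; ctrl[i, ] <- uni
        truth$mixture_group[i] <- "experimental"
        truth$mu_control[i] <- a * mu0 + (1 - a) * mu1
        truth$mu_experimental[i] <- a * mu0 + (1 - a) * mu1
      } else {
        ctrl[i, ] <- mix; expr[i, ] <- uni
        truth$mixture_group[i] <- "control"
        truth$mu_control[i] <- a * mu0 + (1 - a) * mu1
        truth$mu_experimental[i] <- a * mu0 + (1 - a) * mu1
      }
      truth$var_control[i] <- truth$var_experimental[i] <- sg^2
      truth$mu0[i] <- mu0; truth$mu1[i] <- mu1; truth$alpha[i] <- a
    } else {
      delta <- switch(cl,
                      null = runif1(config$null_mean_diff_range),
                      up   = runif1(config$de_mean_diff_range),
                      down = -runif1(config$de_mean_diff_range))
      vdiff <- runif1(if (cl == "null") config$null_var_diff_range
                      else config$de_var_diff_range)
      big_var_in_experimental <- stats::runif(1) < 0.5
      v_ctrl <- if (big_var_in_experimental) 1 else 1 + vdiff
      v_expr <- if (big_var_in_experimental) 1 + vdiff else 1
      mu_c <- config$base_mu
      mu_e <- config$base_mu + delta
      ctrl[i, ] <- rlnorm_log(n, mu_c, sqrt(v_ctrl))
      expr[i, ] <- rlnorm_log(n, mu_e, sqrt(v_expr))
      truth$mu_control[i] <- mu_c; truth$mu_experimental[i] <- mu_e
      truth$var_control[i] <- v_ctrl; truth$var_experimental[i] <- v_expr
    }
  }
  colnames(ctrl) <- sprintf("control%02d", seq_len(n))
  colnames(expr) <- sprintf("case%02d", seq_len(n))
  data <- expression_dataset(ctrl, expr, genes = truth$gene)
  list(data = data, truth = truth)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Writes three TSV files into `directory`: `expression.tsv` (gene column plus
#' all arrays), `groups.tsv` (`sample`, `group` with values
#' `control`/`experimental`), and `truth.tsv` (the ground-truth table). The
#' expression file round-trips through [read_expression_matrix()].
#'
#' @param sim result of [simulate_microarray()].
#' @param directory output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_sim_fixture <- function(sim, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  data <- sim$data
  mat <- cbind(data$control, data$experimental)
  expr_df <- data.frame(gene = data$genes, mat, check.names = FALSE,
                        stringsAsFactors = FALSE)
  paths <- file.path(directory, c("expression.tsv", "groups.tsv", "truth.tsv"))
  utils::write.table(expr_df, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  groups <- data.frame(sample = colnames(mat),
                       group = rep(c("control", "experimental"),
                                   c(ncol(data$control), ncol(data$experimental))),
                       stringsAsFactors = FALSE)
  utils::write.table(groups, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
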