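make_data <- function(ctrl, expr, genes = NULL) {
  expression_dataset(ctrl, expr, genes = genes)
}

test_that("per-gene statistics on toy datasets", {
  set.seed(51)
  ctrl <- rbind(rnorm(10), rnorm(10))
  expr <- rbind(ctrl[1, ] + 10, ctrl[2, ])      # gene 1 fully separated, gene 2 identical
  data <- make_data(ctrl, expr, genes = c("sep", "same"))
  st <- compute_gene_stats(data)
  expect_equal(st$auc[st$gene == "sep"], 1.0)
  expect_equal(st$auc[st$gene == "same"], 0.5)
  expect_gt(st$ovl[st$gene == "same"], 0.99)
  expect_lt(st$ovl[st$gene == "sep"], 0.05)
})

test_that("degenerate genes are reported, not fatal", {
  set.seed(52)
  ctrl <- rbind(rep(1, 6), rnorm(6))
  expr <- rbind(rnorm(6), rnorm(6))
  data <- make_data(ctrl, expr, genes = c("flat", "ok"))
  fit <- arrow_fit(data)
  expect_identical(as.character(fit$stats$label[fit$stats$gene == "flat"]),
                   "UNDETERMINED")
  expect_match(fit$stats$error[fit$stats$gene == "flat"], "degenerate")
  expect_false(is.na(fit$stats$ovl[fit$stats$gene == "ok"]))
})

test_that("classification regions: UP, DOWN, NS from stated statistics", {
  stats <- data.frame(gene = c("a", "b", "c"),
                      ovl = c(0.2, 0.9, 0.2),
                      auc = c(0.95, 0.5, 0.05),
                      error = NA_character_, stringsAsFactors = FALSE)
  set.seed(53)
  data <- make_data(matrix(rnorm(9), 3), matrix(rnorm(9), 3),
                    genes = c("a", "b", "c"))
  out <- select_genes(stats, data)
  expect_identical(as.character(out$label), c("UP", "NS", "DOWN"))
})

test_that("unequal-variance unimodal candidate reverts to NS (step 2)", {
  set.seed(1)
  ctrl <- matrix(rnorm(50, 0, 1), 1)
  expr <- matrix(rnorm(50, 0, 4), 1)
  data <- make_data(ctrl, expr, genes = "g")
  fit <- arrow_fit(data, thresholds = arrow_thresholds())
  st <- fit$stats
  expect_true(st$candidate)                     # passes step 1 on OVL and AUC
  expect_identical(st$modality, "U")            # unimodal in both groups
  expect_identical(as.character(st$label), "NS")
})

test_that("a mixture gene with matched means is labelled SPECIAL", {
  set.seed(1)
  comp <- rbinom(30, 1, 0.5)
  ctrl <- matrix(rnorm(30, 10 * comp, 1.2), 1)
  expr <- matrix(rnorm(30, 5, 1.2), 1)
  data <- make_data(ctrl, expr, genes = "mix")
  fit <- arrow_fit(data)
  expect_identical(as.character(fit$stats$label), "SPECIAL")
  expect_identical(fit$stats$modality, "C")
})

test_that("labels partition the genes and step 2 only shrinks the candidates", {
  sim <- simulate_microarray(sim_config(p_total = 120, n_up = 10, n_down = 10,
                                        n_special = 8, seed = 55))
  fit <- arrow_fit(sim$data, thresholds = arrow_thresholds(preset = "simulation"))
  counts <- table(fit$stats$label)
  expect_identical(sum(counts), nrow(fit$stats))
  expect_true(all(fit$stats$label[fit$stats$label == "SPECIAL"] %in% "SPECIAL"))
  special <- fit$stats$gene[fit$stats$label == "SPECIAL"]
  cand <- fit$stats$gene[fit$stats$candidate]
  expect_true(all(special %in% cand))
})

test_that("relaxing ovl_max never removes genes from UP/DOWN/candidates", {
  sim <- simulate_microarray(sim_config(p_total = 120, n_up = 10, n_down = 10,
                                        n_special = 8, seed = 56))
  st <- compute_gene_stats(sim$data)
  tight <- select_genes(st, sim$data, arrow_thresholds(ovl_max = 0.3))
  loose <- select_genes(st, sim$data, arrow_thresholds(ovl_max = 0.5))
  for (lab in c("UP", "DOWN")) {
    expect_true(all(tight$gene[tight$label == lab] %in%
                    loose$gene[loose$label == lab]))
  }
  expect_true(all(tight$gene[tight$candidate] %in% loose$gene[loose$candidate]))
})

test_that("threshold objects validate and presets apply", {
  expect_error(arrow_thresholds(auc_up = 0.3), "auc_down < auc_special_low")
  expect_error(arrow_thresholds(ovl_max = 0), "ovl_max")
  expect_equal(arrow_thresholds(preset = "simulation")$ovl_max, 0.3)
  expect_equal(arrow_thresholds(preset = "lymphoma")$ovl_max, 0.5)
  expect_equal(arrow_thresholds(preset = "simulation", ovl_max = 0.4)$ovl_max, 0.4)
})

test_that("matrix + groups interface matches the dataset interface", {
  sim <- simulate_microarray(sim_config(p_total = 20, n_up = 2, n_down = 2,
                                        n_special = 1, seed = 58))
  mat <- cbind(sim$data$control, sim$data$experimental)
  groups <- rep(c("control", "experimental"), each = 30)
  fit_m <- arrow_fit(mat, groups = groups, control = "control")
  fit_d <- arrow_fit(sim$data)
  expect_equal(fit_m$stats$ovl, fit_d$stats$ovl)
  expect_identical(as.character(fit_m$stats$label), as.character(fit_d$stats$label))
})

test_that("fit methods: print, summary, coef, as.data.frame", {
  sim <- simulate_microarray(sim_config(p_total = 30, n_up = 3, n_down = 3,
                                        n_special = 2, seed = 59))
  fit <- arrow_fit(sim$data)
  expect_output(print(fit), "Arrow plot gene selection")
  expect_output(print(summary(fit)), "Label counts")
  cf <- coef(fit)
  expect_identical(dim(cf), c(30L, 2L))
  expect_identical(rownames(cf), sim$truth$gene)
  expect_identical(as.data.frame(fit), fit$stats)
})

test_that("arrow plot file output and legend counts match the stats table", {
  sim <- simulate_microarray(sim_config(p_total = 60, n_up = 6, n_down = 6,
                                        n_special = 4, seed = 60))
  fit <- arrow_fit(sim$data, thresholds = arrow_thresholds(preset = "simulation"))
  png_path <- file.path(tempdir(), "arrow-test.png")
  counts <- arrow_plot_file(fit, png_path)
  expect_true(file.exists(png_path))
  expect_gt(file.size(png_path), 0)
  tab <- table(fit$stats$label)
  expect_identical(unname(counts[["UP"]]), unname(tab[["UP"]]))
  expect_identical(unname(counts[["DOWN"]]), unname(tab[["DOWN"]]))
  expect_identical(unname(counts[["NS"]]), unname(tab[["NS"]]))
  sp_split <- counts[["SPECIAL (E)"]] + counts[["SPECIAL (C)"]] + counts[["SPECIAL (B)"]]
  expect_identical(unname(sp_split), unname(tab[["SPECIAL"]]))
  expect_error(arrow_plot_file(fit, file.path(tempdir(), "arrow.pdf")),
               "unsupported image format")
  unlink(png_path)
})

test_that("an empty dataset plots valid empty axes without crashing", {
  data <- expression_dataset(matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2),
                             genes = character(0))
  fit <- arrow_fit(data)
  expect_identical(nrow(fit$stats), 0L)
  png_path <- file.path(tempdir(), "arrow-empty.png")
  arrow_plot_file(fit, png_path)
  expect_gt(file.size(png_path), 0)
  unlink(png_path)
})
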