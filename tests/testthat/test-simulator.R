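test_that("config defaults match the stated design", {
  cfg <- sim_config()
  expect_identical(cfg$p_total, 10000L)
  expect_identical(cfg$n_per_group, 30L)
  expect_identical(c(cfg$n_up, cfg$n_down, cfg$n_special), c(225L, 225L, 50L))
  expect_equal(cfg$null_mean_diff_range, c(-0.9, 0.9))
  expect_equal(cfg$null_var_diff_range, c(0, 12.25))
  expect_equal(cfg$de_mean_diff_range, c(3.5, 13.5))
  expect_equal(cfg$special_mu1_range, c(7, 17))
  expect_equal(cfg$special_sigma, 1.2)
  expect_equal(cfg$special_alpha, 0.5)
})

test_that("config validation rejects inconsistent designs", {
  expect_error(sim_config(p_total = 10, n_up = 8, n_down = 8), "at most p_total")
  expect_error(sim_config(n_per_group = 1), "at least 2")
  expect_error(sim_config(special_alpha = 1), "special_alpha")
  expect_error(sim_config(special_mu1_range = c(5, 2)), "lower <= upper")
})

test_that("exact class counts and shapes for any valid config", {
  sim <- simulate_microarray(sim_config(p_total = 300, n_up = 20, n_down = 15,
                                        n_special = 5, n_per_group = 8, seed = 61))
  tab <- table(sim$truth$class)
  expect_identical(as.integer(tab[c("null", "up", "down", "special")]),
                   c(260L, 20L, 15L, 5L))
  expect_identical(dim(sim$data), c(300L, 16L))
  expect_identical(sim$truth$gene, sim$data$genes)
  expect_true(all(!is.na(sim$data$control)))
})

test_that("same seed gives bit-identical output; different seed differs", {
  cfg <- sim_config(p_total = 50, n_up = 5, n_down = 5, n_special = 2, seed = 62)
  s1 <- simulate_microarray(cfg)
  s2 <- simulate_microarray(cfg)
  expect_identical(s1$data$control, s2$data$control)
  expect_identical(s1$data$experimental, s2$data$experimental)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_microarray(cfg, seed = 63)
  expect_false(identical(s1$data$control, s3$data$control))
})

test_that("enlarging p_total leaves earlier genes unchanged", {
  small <- simulate_microarray(sim_config(p_total = 50, n_up = 5, n_down = 5,
                                          n_special = 2, seed = 64))
  big <- simulate_microarray(sim_config(p_total = 80, n_up = 5, n_down = 5,
                                        n_special = 2, seed = 64))
  expect_identical(big$data$control[1:50, ], small$data$control)
  expect_identical(big$data$experimental[1:50, ], small$data$experimental)
})

test_that("special-gene mixture mean: mu0 = 3.5, mu1 = 17, alpha = 0.5, n = 5000", {
  cfg <- sim_config(p_total = 1, n_up = 0, n_down = 0, n_special = 1,
                    n_per_group = 5000, special_mu1_range = c(17, 17), seed = 65)
  sim <- simulate_microarray(cfg)
  mixture <- if (sim$truth$mixture_group == "control") {
    sim$data$control[1, ]
  } else {
    sim$data$experimental[1, ]
  }
  expect_lt(abs(mean(mixture) - 10.25), 0.15)
  # the unimodal group shares the mean
  other <- if (sim$truth$mixture_group == "control") {
    sim$data$experimental[1, ]
  } else {
    sim$data$control[1, ]
  }
  expect_lt(abs(mean(other) - 10.25), 0.15)
})

test_that("post-log values of a unimodal gene are symmetric (|g1| < 0.2, n = 5000)", {
  cfg <- sim_config(p_total = 1, n_up = 0, n_down = 0, n_special = 0,
                    n_per_group = 5000, null_var_diff_range = c(0, 0), seed = 66)
  sim <- simulate_microarray(cfg)
  expect_lt(abs(oracle_skewness(sim$data$control[1, ])), 0.2)
  expect_lt(abs(oracle_skewness(sim$data$experimental[1, ])), 0.2)
})

test_that("fixture files round-trip through the reader", {
  sim <- simulate_microarray(sim_config(p_total = 12, n_up = 2, n_down = 2,
                                        n_special = 1, n_per_group = 4, seed = 67))
  dir <- file.path(tempdir(), "simfix")
  paths <- write_sim_fixture(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_expression_matrix(file.path(dir, "expression.tsv"),
                                 file.path(dir, "groups.tsv"))
  expect_equal(back$control, sim$data$control, tolerance = 1e-9)
  expect_equal(back$experimental, sim$data$experimental, tolerance = 1e-9)
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  expect_identical(table(truth$class), table(sim$truth$class))
  unlink(dir, recursive = TRUE)
})
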