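test_that("config validation enforces the stated design", {
  expect_error(simulation_config(doses = c(1, 1, 2)), "strictly increasing")
  expect_error(simulation_config(shared_fraction = 1.2), "shared_fraction")
  expect_error(simulation_config(effect_size = -1), "effect_size")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  cfg <- simulation_config()
  expect_equal(length(cfg$doses), 6)
  expect_equal(max(cfg$doses) / min(cfg$doses), 243, tolerance = 1e-9)
  expect_equal(cfg$n_genes, 978)
  expect_equal(cfg$J, 3)
})

test_that("generators are deterministic given the seed", {
  cfg <- simulation_config(n_genes = 15, n_cell_lines = 1, n_drugs = 2,
                           n_classes = 1, time_points = 24, seed = 47)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(SummarizedExperiment::assay(a$expression),
                   SummarizedExperiment::assay(b$expression))
  cfg2 <- simulation_config(n_genes = 15, n_cell_lines = 1, n_drugs = 2,
                            n_classes = 1, time_points = 24, seed = 48)
  c2 <- simulate_expression(cfg2)
  expect_false(identical(SummarizedExperiment::assay(a$expression),
                         SummarizedExperiment::assay(c2$expression)))
  expect_identical(simulate_counts(cfg)$counts$count,
                   simulate_counts(cfg)$counts$count)
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_expression(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero effect size makes treated wells exchangeable with controls", {
  cfg <- simulation_config(n_genes = 40, n_cell_lines = 1, n_drugs = 4,
                           n_classes = 2, time_points = 24, effect_size = 0,
                           plate_effect_sd = 0, seed = 49)
  se <- simulate_expression(cfg)$expression
  x <- SummarizedExperiment::assay(se)
  treated <- as.numeric(x[, se$drug != VEHICLE])
  control <- as.numeric(x[, se$drug == VEHICLE])
  expect_gt(t.test(treated, control)$p.value, 0.01)
})

test_that("planted directions are unit norm and shared when universal", {
  cfg <- simulation_config(n_genes = 50, n_cell_lines = 3, n_drugs = 4,
                           n_classes = 2, shared_fraction = 1,
                           time_points = 24, seed = 51)
  sim <- simulate_expression(cfg)
  expect_true(all(abs(vapply(sim$truth$directions,
                             function(v) sum(v^2), numeric(1)) - 1) < 1e-9))
  tr <- sim$truth$condition_truth
  # one direction key per class regardless of cell line
  for (cl in unique(tr$class)) {
    expect_equal(length(unique(tr$direction_key[tr$class == cl])), 1)
  }
  # with shared_fraction = 0, each cell line gets its own direction
  cfg0 <- simulation_config(n_genes = 50, n_cell_lines = 3, n_drugs = 4,
                            n_classes = 2, shared_fraction = 0,
                            time_points = 24, seed = 51)
  tr0 <- simulate_expression(cfg0)$truth$condition_truth
  for (cl in unique(tr0$class)) {
    expect_equal(length(unique(tr0$direction_key[tr0$class == cl])), 3)
  }
})

test_that("planted amplitude saturates with dose", {
  cfg <- simulation_config(n_genes = 20, n_cell_lines = 1, n_drugs = 1,
                           n_classes = 1, time_points = 24, seed = 53)
  tr <- simulate_expression(cfg)$truth$condition_truth
  tr <- tr[order(tr$concentration), ]
  expect_true(all(diff(tr$amplitude) > 0))
  # saturating link never exceeds effect_size x max sensitivity
  expect_lt(max(tr$amplitude), cfg$effect_size * cfg$sensitivity_range[2])
})

test_that("count generator respects the planted GR regimes", {
  pars <- data.frame(drug = c("drug001", "drug002"), cell_line = "line01",
                     GR_inf = c(1, -1), GEC50 = c(1, 0.1), hill = c(2, 3))
  cfg <- simulation_config(n_genes = 10, n_cell_lines = 1, n_drugs = 2,
                           n_classes = 1, gr_params = pars,
                           count_noise_sd = 0.01, seed = 55)
  simc <- simulate_counts(cfg)
  grt <- gr_table(simc$counts)
  # GR_inf = 1: resistant at every dose
  expect_true(all(abs(grt$GR[grt$drug == "drug001"] - 1) < 0.1))
  # GR_inf = -1 and c >> GEC50: treated counts fall below the day-0 plate
  hi <- simc$counts$drug == "drug002" & simc$counts$concentration == 10
  day0 <- trimmed_mean_day0(simc$counts$count[simc$counts$time_h == 0])
  expect_true(all(simc$counts$count[hi] < day0))
  expect_error(simulation_config(day0_count = 0), "day0_count")
})

test_that("combination generator plants the requested interaction", {
  cfg <- simulation_config(n_genes = 10, n_cell_lines = 1, n_drugs = 2,
                           n_classes = 1, seed = 57)
  expect_error(simulate_combo(cfg, "weird"), "arg")
  g <- simulate_combo(cfg, "bliss_independent")$truth$grid
  eff <- (1 - g$GR_A) + (1 - g$GR_B) - (1 - g$GR_A) * (1 - g$GR_B)
  expect_equal(g$GR_AB, 1 - eff, tolerance = 1e-12)
  gs <- simulate_combo(cfg, "synergistic", planted_eob = 0.4)$truth$grid
  interior <- gs$conc_a > 0 & gs$conc_b > 0
  expect_equal(unique(gs$planted_eob[interior]), 0.4)
  expect_equal(unique(gs$planted_eob[!interior]), 0)
})
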