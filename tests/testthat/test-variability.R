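test_that("SCS coefficient of variation across cell lines", {
  tab <- data.frame(cell_line = c("a", "b", "c"), drug = "d1",
                    concentration = 1, target_class = "k",
                    SCS = c(1, 2, 3))
  out <- scs_cv(tab)
  expect_equal(out$cv, 0.5)  # mean 2, sample sd 1
  tab$SCS <- 2
  expect_equal(scs_cv(tab)$cv, 0)
  # non-positive mean is skipped with a flag
  tab$SCS <- c(-1, 0, 1)
  out2 <- scs_cv(tab)
  expect_true(out2$skipped)
  expect_true(is.na(out2$cv))
  # single cell line: no CV
  expect_null(scs_cv(tab[1, ]))
})

test_that("GR_AOC standard deviation across cell lines", {
  prof <- data.frame(cell_line = c("a", "b"), drug = "d1",
                     target_class = "k", GR_AOC = c(0.2, 0.4))
  expect_equal(gr_aoc_sd(prof)$sd, sqrt(0.02), tolerance = 1e-6)
  expect_equal(gr_aoc_sd(prof)$sd, 0.1414, tolerance = 1e-3)
  prof$GR_AOC <- 0.3
  expect_equal(gr_aoc_sd(prof)$sd, 0)
  expect_null(gr_aoc_sd(prof[1, ]))
})

test_that("universal classes vary less across lines than specific ones", {
  cfg <- simulation_config(n_genes = 60, n_cell_lines = 3, n_drugs = 8,
                           n_classes = 4, shared_fraction = 0.5,
                           time_points = 24, effect_size = 12,
                           noise_sd = 0.4, seed = 41)
  sim <- simulate_expression(cfg)
  batches <- suppressMessages(assemble_batches(sim$expression))
  scs <- do.call(rbind, lapply(seq_along(batches), function(i) {
    batch_scs(batch_chdir(batches[[i]]), n_null = 500, seed = 50 + i)
  }))
  cvs <- scs_cv(scs)
  med <- class_medians(cvs, "cv")
  ty <- sim$truth$class_type[med$target_class]
  expect_lt(median(med$median[ty == "universal"]),
            median(med$median[ty == "specific"]))
})

test_that("dose-shift geometry separates rotating classes", {
  cfg <- simulation_config(n_genes = 80, n_cell_lines = 3, n_drugs = 16,
                           n_classes = 2, shared_fraction = 1,
                           rotation_classes = 1, time_points = 24,
                           effect_size = 15, noise_sd = 0.3, seed = 43)
  sim <- simulate_expression(cfg)
  batches <- suppressMessages(assemble_batches(sim$expression))
  cds <- lapply(batches, batch_chdir)
  # compare two doses where the signal is well above noise, so that the
  # stable class's shift reflects replicate noise rather than weak signal
  ds <- dose_shift(cds, dose_low = cfg$doses[4], dose_high = max(cfg$doses))
  expect_true(all(ds$shifts$distance >= 0 & ds$shifts$distance <= 2))
  rot <- ds$shifts$distance[ds$shifts$target_class == "class01"]
  uni <- ds$shifts$distance[ds$shifts$target_class == "class02"]
  expect_gte(length(rot), 20)
  # rotating class stochastically dominates the stable one
  expect_lt(wilcox.test(rot, uni, alternative = "greater")$p.value, 0.01)
  # amplitude-only (stable) class shifts look like replicate noise: far
  # below the between-class baseline
  expect_lt(median(uni), median(ds$baseline) / 2)

  # identical signatures at both doses give zero shift
  fake <- cds[[1]]
  lo <- fake$conditions$concentration == cfg$doses[4]
  hi <- fake$conditions$concentration == max(cfg$doses)
  fake$vectors[, hi] <- fake$vectors[, lo]
  ds0 <- dose_shift(fake, cfg$doses[4], max(cfg$doses))
  expect_equal(ds0$shifts$distance, rep(0, nrow(ds0$shifts)), tolerance = 1e-9)
})

test_that("cross-line SD of log10 abundance and the two-group test", {
  m <- matrix(c(10, 100, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("l1", "l2")))
  out <- cross_line_sd(m, c("RTK", "signaling"))
  expect_equal(out$sds$sd[1], sd(c(1, 2)))
  expect_equal(out$sds$sd[1], 0.7071, tolerance = 1e-3)
  expect_equal(out$sds$sd[2], 0)
  expect_error(cross_line_sd(matrix(c(-1, 2, 3, 4), 2), c("a", "b")),
               "positive")

  # planted high-variance group vs low-variance group, 20 entities each
  withr::local_seed(45)
  high <- matrix(10^rnorm(20 * 6, 2, 1), 20, 6)
  low <- matrix(10^rnorm(20 * 6, 2, 0.1), 20, 6)
  ab <- rbind(high, low)
  rownames(ab) <- sprintf("e%02d", 1:40)
  res <- cross_line_sd(ab, rep(c("RTK", "signaling"), each = 20),
                       test_pair = c("RTK", "signaling"))
  expect_lt(res$test$p, 0.01)
})

test_that("rank correlation handles ties like the rank-and-Pearson oracle", {
  expect_equal(rank_correlation(1:10, 2 * (1:10))$rho, 1)
  expect_equal(rank_correlation(1:10, -(1:10))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 6)
  y <- c(2.0, 1.0, 3.5, 3.0, 4.0, 4.0)
  out <- rank_correlation(x, y)
  # brute-force oracle: average ranks then plain Pearson
  oracle <- cor(rank(x), rank(y))
  expect_equal(out$rho, oracle, tolerance = 1e-12)
  expect_true(out$p > 0 && out$p <= 1)
  cst <- rank_correlation(rep(1, 5), 1:5)
  expect_equal(cst$flag, "constant_input")
  expect_error(rank_correlation(1:2, 1:2), "n >= 3")
})
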