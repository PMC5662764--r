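make_two_group_vectors <- function(n_per = 20, G = 50, noise = 0.05,
                                   seed = 11) {
  e1 <- c(1, rep(0, G - 1)); e2 <- c(0, 1, rep(0, G - 2))
  v <- cbind(noisy_directions(e1, n_per, noise, seed),
             noisy_directions(e2, n_per, noise, seed + 1))
  colnames(v) <- sprintf("c%02d", seq_len(2 * n_per))
  list(vectors = v, labels = rep(1:2, each = n_per))
}

test_that("well-separated planted groups are recovered exactly", {
  fix <- make_two_group_vectors()
  model <- fuzzy_cluster(fix$vectors, k = 2, n_runs = 11, seed = 1)
  expect_false(anyNA(model$assignment))
  expect_equal(adjusted_rand_index(model$assignment, fix$labels), 1.0)
  # memberships row-stochastic
  expect_equal(unname(rowSums(model$memberships)),
               rep(1, ncol(fix$vectors)), tolerance = 1e-6)
  # assigned conditions clear the cutoff in the reported run
  mx <- apply(model$memberships, 1, max)
  expect_true(all(mx[!is.na(model$assignment)] >= 0.55 - 1e-6))
})

test_that("identical vectors split memberships and stay unassigned", {
  v <- matrix(rep(c(1, 0, 0), 8), nrow = 3)
  model <- fuzzy_cluster(v, k = 2, n_runs = 5, seed = 2)
  expect_true(all(is.na(model$assignment)))
  expect_equal(unname(model$memberships[, 1]), rep(0.5, 8), tolerance = 1e-6)
})

test_that("a vector equidistant from two planted centroids is unassigned", {
  fix <- make_two_group_vectors(n_per = 15, noise = 0.02, seed = 3)
  G <- nrow(fix$vectors)
  mid <- (c(1, rep(0, G - 1)) + c(0, 1, rep(0, G - 2))) / sqrt(2)
  v <- cbind(fix$vectors, mid = mid)
  model <- fuzzy_cluster(v, k = 2, n_runs = 11, seed = 4)
  expect_true(is.na(model$assignment["mid"]))
  expect_false(anyNA(model$assignment[1:30]))
})

test_that("errors on impossible requests", {
  v <- make_two_group_vectors(n_per = 3)$vectors
  expect_error(fuzzy_cluster(v, k = 10), "exceeds")
  expect_error(fuzzy_cluster(v[, 0], k = 1), "no signatures")
})

test_that("unassigned fraction is monotone in the membership cutoff", {
  fix <- make_two_group_vectors(n_per = 15, noise = 0.4, seed = 6)
  cuts <- c(0.55, 0.75, 0.95)
  frac <- vapply(cuts, function(ct) {
    m <- fuzzy_cluster(fix$vectors, k = 2, membership_cutoff = ct,
                       n_runs = 11, seed = 7)
    mean(is.na(m$assignment))
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("consensus assignment is reproducible across master seeds", {
  cfg <- small_expression_config(seed = 31)
  sim <- simulate_expression(cfg)
  batches <- suppressMessages(assemble_batches(sim$expression))
  cds <- lapply(batches, batch_chdir)
  vectors <- do.call(cbind, lapply(cds, `[[`, "vectors"))
  conditions <- do.call(rbind, lapply(cds, `[[`, "conditions"))
  scs <- do.call(rbind, lapply(cds, batch_scs, n_null = 500, seed = 8))
  keep <- scs$SCS > 1.3
  v <- vectors[, keep]
  m1 <- fuzzy_cluster(v, k = 4, n_runs = 31, seed = 100)
  m2 <- fuzzy_cluster(v, k = 4, n_runs = 31, seed = 999)
  both <- !is.na(m1$assignment) & !is.na(m2$assignment)
  expect_gte(adjusted_rand_index(m1$assignment[both], m2$assignment[both]), 0.95)
  expect_gte(mean(both), 0.8)
})

test_that("consensus signatures average members and flag degeneracy", {
  v <- c(0, 3, 4) / 5
  expect_equal(consensus_signature(cbind(v)), v)
  expect_warning(out <- consensus_signature(cbind(v, -v)), "degenerate")
  expect_equal(out, c(0, 0, 0))
  expect_warning(expect_null(consensus_signature(matrix(0, 3, 0))), "empty")
  # averaging reduces noise: consensus is closer to the planted center
  # than a typical member
  center <- c(1, rep(0, 49))
  members <- noisy_directions(center, 30, 0.3, seed = 12)
  cons <- consensus_signature(members)
  member_dists <- apply(members, 2, cosine_distance, b = center)
  expect_lt(cosine_distance(cons, center), mean(member_dists))
})

test_that("network edges follow the interpolated percentile threshold", {
  v <- matrix(rep(c(1, 2, 3), 4), nrow = 3)
  net <- build_network(v, q = 50)
  expect_equal(nrow(net$edges), choose(4, 2))  # all identical: all pairs
  expect_equal(net$threshold, 0)

  withr::local_seed(13)
  r <- matrix(rnorm(50 * 100), 50, 100)
  net2 <- build_network(r, q = 2)
  d <- grsig:::pairwise_cosine_distance(r)
  expect_equal(net2$threshold, unname(quantile(d, 0.02, type = 7)))
  expect_equal(nrow(net2$edges), sum(d <= net2$threshold))
  expect_equal(nrow(net2$edges), 99)  # 2% of 4950, interpolated, tie-free

  # two orthogonal tight groups: edges stay within groups
  fix <- make_two_group_vectors(n_per = 10, noise = 0.02, seed = 14)
  net3 <- build_network(fix$vectors, q = 40)
  grp <- setNames(fix$labels, colnames(fix$vectors))
  expect_true(all(grp[net3$edges$from] == grp[net3$edges$to]))
})

test_that("network export writes SIF and edge/node tables", {
  fix <- make_two_group_vectors(n_per = 4, seed = 15)
  net <- build_network(fix$vectors, q = 10,
                       nodes = data.frame(label = fix$labels))
  sif <- withr::local_tempfile(fileext = ".sif")
  edges <- withr::local_tempfile(fileext = ".tsv")
  nodes <- withr::local_tempfile(fileext = ".csv")
  write_network(net, sif, edges, nodes)
  expect_equal(length(readLines(sif)), nrow(net$edges))
  back <- read.delim(edges)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(read.csv(nodes)$label, fix$labels)
})

test_that("cluster enrichment matches the closed-form binomial tail", {
  # 200 labeled conditions, one cluster of 20 all of a category with
  # global frequency 0.1
  labels <- c(rep("A", 20), rep("B", 180))
  assignment <- c(rep(1L, 20), rep(2L, 180))
  enr <- cluster_enrichment(assignment, labels)
  hit <- enr[enr$cluster == 1 & enr$category == "A", ]
  expect_equal(hit$p, 0.1^20, tolerance = 1e-8)
  expect_equal(hit$global_freq, 0.1)

  # composition identical to global frequencies: no enrichment signal
  labels2 <- rep(c("A", "B"), 50)
  assignment2 <- rep(1:2, each = 50)
  enr2 <- cluster_enrichment(assignment2, labels2)
  expect_true(all(enr2$p > 0.3))

  expect_error(cluster_enrichment(assignment2, labels2[-1]), "lengths")
  labels2[3] <- NA
  expect_error(cluster_enrichment(assignment2, labels2), "unlabeled")
})

test_that("consensus clustering keeps planted classes pure at the planted k", {
  cfg <- small_expression_config(seed = 61, effect_size = 15)
  sim <- simulate_expression(cfg)
  cds <- lapply(suppressMessages(assemble_batches(sim$expression)), batch_chdir)
  scs <- do.call(rbind, lapply(seq_along(cds), function(i) {
    batch_scs(cds[[i]], n_null = 500, seed = 70 + i)
  }))
  vectors <- do.call(cbind, lapply(cds, `[[`, "vectors"))
  keep <- scs$SCS > 1.3
  tr <- sim$truth$condition_truth
  planted <- tr$cluster_label[match(scs$condition_key[keep], tr$condition_key)]
  n_planted <- length(unique(planted))
  model <- fuzzy_cluster(vectors[, keep], k = n_planted, n_runs = 101,
                         seed = 80)
  a <- model$assignment
  purity <- vapply(split(planted[!is.na(a)], a[!is.na(a)]), function(lab) {
    max(table(lab)) / length(lab)
  }, numeric(1))
  expect_gte(min(purity), 0.9)
  # consensus beats the worst single runs (the point of the 101 runs)
  single <- fuzzy_cluster(vectors[, keep], k = n_planted, n_runs = 1,
                          seed = 82)
  expect_gte(adjusted_rand_index(a, planted),
             adjusted_rand_index(single$assignment, planted))
})

test_that("dose-rotating classes enrich top-dose conditions in clusters", {
  cfg <- simulation_config(n_genes = 80, n_cell_lines = 2, n_drugs = 8,
                           n_classes = 1, shared_fraction = 1,
                           rotation_classes = 1, time_points = 24,
                           effect_size = 15, noise_sd = 0.3, seed = 63)
  sim <- simulate_expression(cfg)
  cds <- lapply(suppressMessages(assemble_batches(sim$expression)), batch_chdir)
  scs <- do.call(rbind, lapply(seq_along(cds), function(i) {
    batch_scs(cds[[i]], n_null = 500, seed = 90 + i)
  }))
  vectors <- do.call(cbind, lapply(cds, `[[`, "vectors"))
  keep <- scs$SCS > 1.3
  model <- fuzzy_cluster(vectors[, keep], k = 3, n_runs = 21, seed = 95)
  labels <- ifelse(scs$concentration[keep] == max(cfg$doses),
                   "top_dose", "lower_dose")
  enr <- cluster_enrichment(model$assignment, labels)
  top <- enr[enr$category == "top_dose", ]
  expect_lt(min(top$p), 0.005)
})

test_that("adjusted Rand index behaves at its reference points", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  b <- a; b[a == 2] <- 5  # relabeling does not matter
  expect_equal(adjusted_rand_index(a, b), 1)
  withr::local_seed(16)
  expect_lt(abs(adjusted_rand_index(a, sample(a))), 0.25)
  expect_equal(adjusted_rand_index(c(a, NA), c(a, 1)), 1)  # NA dropped
})
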