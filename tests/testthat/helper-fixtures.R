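# shared fixture builders; everything is generated in code at test time

# small but fully structured screen: 2 cell lines x 1 time point,
# 6 drugs in 3 classes, strong signal
# clear-signal regime (all cell lines respond): unit tests of the
# machinery; the default near-non-responder regime is exercised in the
# acceptance suite
small_expression_config <- function(seed = 7, effect_size = 10, ...) {
  simulation_config(n_genes = 60, n_cell_lines = 2, n_drugs = 6, n_classes = 3,
                    time_points = 24, effect_size = effect_size, noise_sd = 0.4,
                    sensitivity_range = c(0.6, 1.4), seed = seed, ...)
}

# tiny hand-built SummarizedExperiment: 3 genes, 2 plates x (2 controls +
# 1 treated well each)
tiny_se <- function() {
  wells <- rbind(
    well_metadata("P1", "A01", "MCF7", "DMSO", 0, 24, 1),
    well_metadata("P1", "A02", "MCF7", "DMSO", 0, 24, 2),
    well_metadata("P1", "A03", "MCF7", "drugX", 1, 24, 1, "kinase"),
    well_metadata("P2", "A01", "MCF7", "DMSO", 0, 24, 1),
    well_metadata("P2", "A02", "MCF7", "DMSO", 0, 24, 2),
    well_metadata("P2", "A03", "MCF7", "drugX", 1, 24, 2, "kinase")
  )
  values <- matrix(seq(0.5, by = 0.25, length.out = 3 * nrow(wells)), nrow = 3,
                   dimnames = list(paste0("g", 1:3),
                                   paste(wells$plate_id, wells$well, sep = ".")))
  wells$well <- colnames(values)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(wells, row.names = colnames(values)))
}

# columns with a prescribed cosine Gram matrix: crossprod(chol(gram)) == gram
vectors_with_gram <- function(gram) {
  chol(gram)
}

# G x n matrix of unit columns scattered around a direction with
# additive Gaussian noise
noisy_directions <- function(center, n, noise, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(length(center) * n, sd = noise), length(center), n)
    m <- m + center
    sweep(m, 2, sqrt(colSums(m^2)), "/")
  })
}
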