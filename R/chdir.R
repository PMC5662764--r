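#' Shrinkage parameters for the characteristic-direction estimator
#'
#' The per-replicate characteristic direction is a regularized discriminant
#' direction `b = Sigma^-1 (x - mean(C))` where `Sigma` is estimated from
#' the plate's control wells alone (the treated "group" has size 1). Since
#' the control sample covariance `S` is rank-deficient for `N << G`, it is
#' shrunk toward a scaled identity:
#'
#'   `Sigma = (1 - gamma) * S + gamma * nu * I + ridge * I`, with
#'   `nu = trace(S) / G`.
#'
#' `gamma = 1` gives the identity-covariance limit, where the direction is
#' exactly the normalized mean-difference vector.
#'
#' @param gamma shrinkage weight toward the scaled identity, in `[0, 1]`.
#'   Default 0.5.
#' @param ridge small positive diagonal constant for numerical rank safety.
#' @return a `shrinkage_params` list.
#' @export
shrinkage_params <- function(gamma = 0.5, ridge = 1e-8) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma <= 1,
            is.numeric(ridge), length(ridge) == 1, ridge > 0)
  structure(list(gamma = gamma, ridge = ridge), class = "shrinkage_params")
}

# shrunk control covariance for one plate
control_sigma <- function(controls, params) {
  if (ncol(controls) < 2) {
    stop("insufficient controls: need N >= 2 control wells to estimate covariance",
         call. = FALSE)
  }
  G <- nrow(controls)
  S <- stats::cov(t(controls))
  nu <- sum(diag(S)) / G
  Sigma <- (1 - params$gamma) * S
  diag(Sigma) <- diag(Sigma) + params$gamma * nu + params$ridge
  Sigma
}

#' Characteristic direction of one treated replicate
#'
#' Computes the unit-norm discriminant direction separating a single
#' treated expression profile from the same-plate vehicle controls,
#' `b = Sigma^-1 (x - mean(C))` normalized to unit length (see
#' [shrinkage_params()] for `Sigma`). The sign is fixed so that the
#' direction has non-negative projection on the raw difference vector
#' (discriminant directions are otherwise sign-ambiguous).
#'
#' @param controls numeric `G x N` matrix of control profiles (`N >= 2`).
#' @param treated numeric length-`G` treated profile.
#' @param params a [shrinkage_params()] object.
#' @return unit-norm numeric vector of length `G`.
#' @export
characteristic_direction <- function(controls, treated, params = shrinkage_params()) {
  controls <- as.matrix(controls)
  treated <- as.numeric(treated)
  if (nrow(controls) != length(treated)) {
    stop("controls and treated must cover the same genes", call. = FALSE)
  }
  if (nrow(controls) < 2) stop("need G >= 2 genes", call. = FALSE)
  Sigma <- control_sigma(controls, params)
  d <- treated - rowMeans(controls)
  if (sqrt(sum(d^2)) < 1e-12) {
    stop("degenerate signal: treated profile equals the control mean", call. = FALSE)
  }
  R <- chol(Sigma)
  b <- backsolve(R, forwardsolve(t(R), d))
  if (sum(b * d) < 0) b <- -b
  b / sqrt(sum(b^2))
}

#' Batch-average characteristic direction
#'
#' The final signature of a condition is the mean of its per-replicate unit
#' directions, re-normalized to unit length. The pre-normalization
#' magnitude `||mean_j D_ij||` is retained as the condition's `amplitude`
#' in `[0, 1]`: 1 when replicates agree perfectly, small when they point in
#' unrelated directions.
#'
#' @param replicates `G x J` matrix whose columns are unit-norm
#'   per-replicate directions (`J >= 1`).
#' @return a `characteristic_direction` list with elements `vector` (unit
#'   norm), `amplitude`, and `J_used`.
#' @export
batch_average_cd <- function(replicates) {
  replicates <- as.matrix(replicates)
  if (ncol(replicates) < 1) stop("need at least one replicate", call. = FALSE)
  nrm <- sqrt(colSums(replicates^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("replicate directions must be unit norm", call. = FALSE)
  }
  m <- rowMeans(replicates)
  amp <- sqrt(sum(m^2))
  if (amp < 1e-12) {
    stop("degenerate consistency: replicate directions cancel", call. = FALSE)
  }
  structure(list(vector = m / amp, amplitude = amp, J_used = ncol(replicates)),
            class = "characteristic_direction")
}

#' Cosine distance between two vectors
#'
#' `1 - cos(a, b)`, in `[0, 2]`: 0 for parallel, 1 for orthogonal, 2 for
#' antiparallel vectors.
#'
#' @param a,b non-zero numeric vectors of equal length.
#' @return scalar in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("cosine distance undefined for a zero vector",
                                     call. = FALSE)
  1 - sum(a * b) / (na * nb)
}

# all pairwise cosine distances between columns of x, as a dist-style
# lower-triangle vector or full matrix
pairwise_cosine_distance <- function(x, as_matrix = FALSE) {
  nrm <- sqrt(colSums(x^2))
  if (any(nrm < 1e-12)) stop("zero column in cosine distance", call. = FALSE)
  xn <- sweep(x, 2, nrm, "/")
  D <- 1 - crossprod(xn)
  D[D < 0] <- 0
  if (as_matrix) return(D)
  D[lower.tri(D)]
}

#' Characteristic directions for a whole plate batch
#'
#' Computes the per-replicate characteristic direction of every condition
#' in a [assemble_batches()] batch against its plate's controls, then the
#' batch-averaged unit signature per condition. The shrunk control
#' covariance is factorized once per plate and reused for all conditions
#' on that plate.
#'
#' @param batch a `plate_batch`.
#' @param params a [shrinkage_params()] object.
#' @return a `cd_batch` list: `vectors` (`G x M` unit columns, the final
#'   signatures), `conditions` (metadata + `amplitude`, `J_used`),
#'   `replicates` (per-condition `G x J` matrices of unit per-replicate
#'   directions), plus batch identity fields.
#' @export
batch_chdir <- function(batch, params = shrinkage_params()) {
  stopifnot(inherits(batch, "plate_batch"))
  G <- length(batch$gene_ids)
  # one Cholesky factor per plate
  chols <- lapply(batch$controls, function(C) {
    list(R = chol(control_sigma(C, params)), mu = rowMeans(C))
  })

  keep <- logical(batch$M)
  reps <- vector("list", batch$M)
  finals <- matrix(NA_real_, G, batch$M)
  amp <- rep(NA_real_, batch$M)
  for (i in seq_len(batch$M)) {
    X <- batch$treated[[i]]
    Dij <- matrix(NA_real_, G, ncol(X), dimnames = list(NULL, colnames(X)))
    ok <- TRUE
    for (j in seq_len(ncol(X))) {
      pl <- colnames(X)[j]
      f <- chols[[pl]]
      d <- X[, j] - f$mu
      if (sqrt(sum(d^2)) < 1e-12) { ok <- FALSE; break }
      b <- backsolve(f$R, forwardsolve(t(f$R), d))
      if (sum(b * d) < 0) b <- -b
      Dij[, j] <- b / sqrt(sum(b^2))
    }
    if (!ok) {
      warning(sprintf("condition %s: degenerate replicate (equals control mean), dropped",
                      names(batch$treated)[i]), call. = FALSE)
      next
    }
    fin <- tryCatch(batch_average_cd(Dij), error = function(e) NULL)
    if (is.null(fin)) {
      warning(sprintf("condition %s: replicate directions cancel, dropped",
                      names(batch$treated)[i]), call. = FALSE)
      next
    }
    keep[i] <- TRUE
    reps[[i]] <- Dij
    finals[, i] <- fin$vector
    amp[i] <- fin$amplitude
  }

  conditions <- batch$conditions[keep, , drop = FALSE]
  conditions$amplitude <- amp[keep]
  rownames(conditions) <- NULL
  vectors <- finals[, keep, drop = FALSE]
  colnames(vectors) <- conditions$condition_key
  rownames(vectors) <- batch$gene_ids
  reps <- reps[keep]
  names(reps) <- conditions$condition_key
  structure(list(
    cell_line = batch$cell_line, time_h = batch$time_h,
    gene_ids = batch$gene_ids, J = batch$J,
    vectors = vectors, conditions = conditions, replicates = reps
  ), class = "cd_batch")
}

#' @export
print.cd_batch <- function(x, ...) {
  cat(sprintf("cd_batch: %s at %g h — %d condition signatures over %d genes\n",
              x$cell_line, x$time_h, ncol(x$vectors), nrow(x$vectors)))
  invisible(x)
}

#' Write condition signatures as GCT + amplitude table
#'
#' Exports the batch-averaged characteristic directions of one or more
#' `cd_batch` objects as a genes x conditions GCT 1.3 file plus a CSV of
#' `(condition_key, amplitude, J_used)`.
#'
#' @param cds a `cd_batch` or list of them.
#' @param gct_path,csv_path output paths.
#' @return invisibly, the condition table written to `csv_path`.
#' @export
write_cd_gct <- function(cds, gct_path, csv_path) {
  if (inherits(cds, "cd_batch")) cds <- list(cds)
  vectors <- do.call(cbind, lapply(cds, `[[`, "vectors"))
  conditions <- do.call(rbind, lapply(cds, `[[`, "conditions"))
  cd <- S4Vectors::DataFrame(
    well = conditions$condition_key,
    plate_id = "CD", cell_line = conditions$cell_line,
    drug = conditions$drug, concentration = conditions$concentration,
    time_h = conditions$time_h, replicate = 1L,
    row.names = make.unique(conditions$condition_key)
  )
  colnames(vectors) <- rownames(cd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vectors), colData = cd)
  write_gct(se, gct_path)
  out <- conditions[, c("condition_key", "amplitude", "J_used")]
  utils::write.csv(out, csv_path, row.names = FALSE)
  invisible(out)
}
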