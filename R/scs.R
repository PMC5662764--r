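#' Replicate dispersion of a condition's characteristic directions
#'
#' The mean of all pairwise cosine distances between the `J` per-replicate
#' unit directions of one condition:
#' `S_i = 1 - sum_{j<j'} cos(D_ij, D_ij') / choose(J, 2)`.
#' Small values mean the replicates agree.
#'
#' @param replicates `G x J` matrix of unit-norm columns, `J >= 2`.
#' @return scalar in `[0, 2]`.
#' @export
replicate_dispersion <- function(replicates) {
  replicates <- as.matrix(replicates)
  J <- ncol(replicates)
  if (J < 2) stop("insufficient replicates: dispersion needs J >= 2", call. = FALSE)
  mean(pairwise_cosine_distance(replicates))
}

#' Empirical null for replicate dispersion
#'
#' Draws `J` per-replicate directions at random (without replacement
#' within a draw) from the pool of all `M * J` replicate directions in a
#' batch and records their mean pairwise cosine distance; repeated
#' `n_null` times. This is the dispersion expected when "replicates" are
#' in fact unrelated perturbations, against which an observed `S_i` is
#' compared. The pool is used as-is rather than an isotropic model because
#' gene expression values are strongly dependent.
#'
#' When `strata` (the plate of origin of each pool vector) is supplied,
#' each draw first picks `J` distinct plates and then one vector from
#' each — the same one-per-plate structure that real replicate sets have.
#' This matters because directions computed against the same control
#' wells share the control-mean estimate and are therefore slightly
#' positively correlated; an unconstrained draw mixes such same-plate
#' pairs into the null and makes the score conservative, while the
#' stratified draw keeps null and observed dispersions exchangeable under
#' the null hypothesis (see the methods vignette).
#'
#' @param pool `G x P` matrix of all replicate directions in the batch
#'   (columns need not be exactly unit norm; they are normalized).
#' @param J number of vectors per draw (the batch's replicate count).
#' @param n_null number of draws (default 10000).
#' @param seed optional integer seed; the draw is deterministic given it.
#' @param strata optional length-`P` plate label per pool column; when
#'   given, draws take one vector per plate.
#' @return a `null_distribution` list: `values`, `J`, `pool_size`, `seed`.
#' @export
build_null <- function(pool, J, n_null = 10000, seed = NULL, strata = NULL) {
  pool <- as.matrix(pool)
  P <- ncol(pool)
  if (J < 2) stop("J must be >= 2", call. = FALSE)
  if (P < J) stop(sprintf("pool (%d) smaller than J (%d)", P, J), call. = FALSE)
  nrm <- sqrt(colSums(pool^2))
  if (any(nrm < 1e-12)) stop("zero vector in null pool", call. = FALSE)
  if (!is.null(strata)) {
    if (length(strata) != P) stop("strata must label every pool column", call. = FALSE)
    by_plate <- split(seq_len(P), strata)
    if (length(by_plate) < J) {
      stop(sprintf("only %d plate(s) in pool but J = %d", length(by_plate), J),
           call. = FALSE)
    }
  }
  Gm <- crossprod(sweep(pool, 2, nrm, "/"))  # P x P cosine gram
  npair <- J * (J - 1)
  values <- with_seed(seed, {
    if (is.null(strata)) {
      vapply(seq_len(n_null), function(i) {
        id <- sample.int(P, J)
        1 - (sum(Gm[id, id]) - J) / npair
      }, numeric(1))
    } else {
      nP <- length(by_plate)
      vapply(seq_len(n_null), function(i) {
        pl <- if (nP == J) seq_len(nP) else sample.int(nP, J)
        id <- vapply(by_plate[pl], function(ix) ix[sample.int(length(ix), 1)],
                     integer(1))
        1 - (sum(Gm[id, id]) - J) / npair
      }, numeric(1))
    }
  })
  values[values < 0] <- 0
  structure(list(values = values, J = J, pool_size = P, seed = seed),
            class = "null_distribution")
}

#' Signature Consistency Score
#'
#' One-tail (lower-end) comparison of an observed replicate dispersion
#' `S_i` with the empirical null: `p = (1 + #{S_n <= S_i}) / (n_null + 1)`
#' and `SCS = -log10(p)`. The add-one pseudo-count keeps the score finite
#' when `S_i` beats every null draw, capping SCS at `log10(n_null + 1)`;
#' ties are counted against the condition (conservative). `SCS > 1.3`
#' corresponds to `p < 0.05`.
#'
#' @param S_i observed mean pairwise cosine distance.
#' @param null a [build_null()] result.
#' @return a one-row `data.frame`: `S_i`, `p_value`, `SCS`, `n_null`.
#' @export
score_scs <- function(S_i, null) {
  stopifnot(inherits(null, "null_distribution"), length(null$values) > 0)
  n <- length(null$values)
  p <- (1 + sum(null$values <= S_i)) / (n + 1)
  data.frame(S_i = S_i, p_value = p, SCS = -log10(p), n_null = n)
}

#' Consistency scores for a whole batch
#'
#' Builds the batch's null distribution from the pool of all replicate
#' directions (plate-stratified draws; see [build_null()]) and scores
#' every condition with `J >= 2` replicates. When conditions carry
#' unequal replicate counts (missing plates), a separate null is built
#' per distinct `J`.
#'
#' @param cds a [batch_chdir()] result.
#' @param n_null null draws per distinct `J` (default 10000).
#' @param seed optional integer master seed.
#' @return `data.frame` with one row per scoreable condition:
#'   condition metadata, `amplitude`, `S_i`, `p_value`, `SCS`, `n_null`.
#' @export
batch_scs <- function(cds, n_null = 10000, seed = NULL) {
  stopifnot(inherits(cds, "cd_batch"))
  pool <- do.call(cbind, cds$replicates)
  plates <- unlist(lapply(cds$replicates, colnames), use.names = FALSE)
  conditions <- cds$conditions
  Js <- vapply(cds$replicates, ncol, integer(1))
  scoreable <- which(Js >= 2)
  if (length(scoreable) == 0) {
    warning("no condition has J >= 2; nothing to score", call. = FALSE)
    return(conditions[0, ])
  }
  nulls <- list()
  for (J in sort(unique(Js[scoreable]))) {
    nulls[[as.character(J)]] <- build_null(pool, J, n_null = n_null,
                                           seed = child_seed(seed, J),
                                           strata = plates)
  }
  rows <- lapply(scoreable, function(i) {
    S_i <- replicate_dispersion(cds$replicates[[i]])
    cbind(conditions[i, , drop = FALSE],
          score_scs(S_i, nulls[[as.character(Js[i])]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
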