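#' Consensus fuzzy c-means clustering of signatures on cosine geometry
#'
#' Clusters unit-norm characteristic-direction signatures with fuzzy
#' c-means (FCM). Inputs are unit-normalized, so the squared Euclidean
#' distance used by the FCM objective equals twice the cosine distance and
#' the objective ordering on cosine geometry is preserved without a
#' bespoke cosine FCM.
#'
#' The algorithm is run `n_runs` times from independent random
#' initializations. Because cluster labels are arbitrary per run, each
#' run's centroids are aligned to run 1 by greedy maximum-cosine matching.
#' A condition is then assigned to the cluster it lands in most often
#' among the runs where its (aligned) maximum membership reaches
#' `membership_cutoff`; conditions that never reach the cutoff stay
#' unassigned (`NA`). Ties are broken toward the cluster with the higher
#' mean membership across runs. Reported soft memberships come from the
#' run whose final objective is the median across runs.
#'
#' The low default fuzzifier (1.22) yields near-crisp memberships; the
#' 55% cutoff discards conditions sitting between clusters. Empty
#' clusters can occur at large `k` and are retained as empty.
#'
#' @param vectors `G x n` matrix whose columns are unit-norm signatures
#'   (typically the `vectors` of [batch_chdir()] results filtered to
#'   `SCS > 1.3`).
#' @param k number of clusters (default 20).
#' @param exponent FCM fuzzifier `m > 1` (default 1.22).
#' @param membership_cutoff minimum max-membership for a run to count
#'   toward assignment (default 0.55).
#' @param n_runs number of independent FCM runs (default 101).
#' @param seed optional master seed; each run derives its own stream.
#' @param max_iter,tol FCM convergence controls.
#' @return a `cluster_model` list: `memberships` (`n x k`, rows sum to 1),
#'   `assignment` (cluster id or `NA` per condition), `centroids`
#'   (`k x G`), `stability` (fraction of qualifying runs agreeing with the
#'   final assignment), `n_qualifying`, and the parameters.
#' @export
fuzzy_cluster <- function(vectors, k = 20, exponent = 1.22,
                          membership_cutoff = 0.55, n_runs = 101,
                          seed = NULL, max_iter = 300, tol = 1e-6) {
  vectors <- as.matrix(vectors)
  n <- ncol(vectors)
  if (n == 0) stop("no signatures to cluster", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the number of conditions (%d)", k, n),
                  call. = FALSE)
  stopifnot(exponent > 1, membership_cutoff > 0, membership_cutoff <= 1)
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm < 1e-12)) stop("zero signature vector", call. = FALSE)
  X <- t(sweep(vectors, 2, nrm, "/"))  # n x G, rows are unit items

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    runs[[r]] <- with_seed(child_seed(seed, r),
                           fcm_run(X, k, exponent, max_iter, tol))
  }

  ref <- runs[[1]]$V
  votes <- matrix(0L, n, k)
  qual_runs <- integer(n)
  mean_membership <- matrix(0, n, k)
  for (r in seq_len(n_runs)) {
    perm <- match_centroids(runs[[r]]$V, ref)
    U <- runs[[r]]$U[, order(perm), drop = FALSE]  # aligned columns
    mean_membership <- mean_membership + U
    mx <- max.col(U, ties.method = "first")
    mv <- U[cbind(seq_len(n), mx)]
    ok <- mv >= membership_cutoff
    qual_runs <- qual_runs + ok
    idx <- cbind(which(ok), mx[ok])
    votes[idx] <- votes[idx] + 1L
    runs[[r]]$perm <- perm
  }
  mean_membership <- mean_membership / n_runs

  assignment <- rep(NA_integer_, n)
  stability <- rep(NA_real_, n)
  for (i in which(qual_runs > 0)) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1) best <- best[which.max(mean_membership[i, best])]
    assignment[i] <- best
    stability[i] <- votes[i, best] / qual_runs[i]
  }

  objectives <- vapply(runs, `[[`, numeric(1), "objective")
  med <- order(objectives)[ceiling(n_runs / 2)]
  Umed <- runs[[med]]$U[, order(runs[[med]]$perm), drop = FALSE]
  Vmed <- runs[[med]]$V[runs[[med]]$perm, , drop = FALSE]
  dimnames(Umed) <- list(colnames(vectors), NULL)
  names(assignment) <- colnames(vectors)

  structure(list(
    memberships = Umed, assignment = assignment, centroids = Vmed,
    stability = stability, n_qualifying = qual_runs,
    objectives = objectives, k = k, exponent = exponent,
    membership_cutoff = membership_cutoff, n_runs = n_runs, seed = seed
  ), class = "cluster_model")
}

# one fuzzy c-means run: X is items x features, returns memberships U
# (items x k), centroids V (k x features), final objective
fcm_run <- function(X, k, m, max_iter, tol) {
  n <- nrow(X)
  U <- matrix(stats::runif(n * k), n, k)
  U <- U / rowSums(U)
  obj <- Inf
  x2 <- rowSums(X^2)
  for (it in seq_len(max_iter)) {
    Um <- U^m
    cs <- colSums(Um)
    cs[cs < 1e-300] <- 1e-300
    V <- (t(Um) %*% X) / cs
    d2 <- outer(x2, rowSums(V^2), "+") - 2 * X %*% t(V)
    d2[d2 < 1e-12] <- 1e-12
    W <- d2^(-1 / (m - 1))
    Unew <- W / rowSums(W)
    obj <- sum(Unew^m * d2)
    if (max(abs(Unew - U)) < tol) { U <- Unew; break }
    U <- Unew
  }
  list(U = U, V = V, objective = obj)
}

# greedy maximum-cosine matching of rows of V onto rows of ref;
# returns perm such that V[perm[j], ] corresponds to ref[j, ]
match_centroids <- function(V, ref) {
  k <- nrow(ref)
  nv <- sqrt(rowSums(V^2)); nv[nv < 1e-12] <- 1e-12
  nr <- sqrt(rowSums(ref^2)); nr[nr < 1e-12] <- 1e-12
  S <- (ref / nr) %*% t(V / nv)  # k x k cosine similarity
  perm <- integer(k)
  for (step in seq_len(k)) {
    ij <- arrayInd(which.max(S), dim(S))
    perm[ij[1]] <- ij[2]
    S[ij[1], ] <- -Inf
    S[, ij[2]] <- -Inf
  }
  perm
}

#' Consensus signature of a cluster
#'
#' The arithmetic mean of the member signatures (not re-normalized, so
#' its magnitude reflects member agreement).
#'
#' @param members `G x m` matrix of member signatures, `m >= 1`.
#' @return numeric vector of length `G`, or `NULL` with a warning for an
#'   empty cluster. A near-zero mean (members cancel) triggers a
#'   degeneracy warning.
#' @export
consensus_signature <- function(members) {
  members <- as.matrix(members)
  if (ncol(members) == 0) {
    warning("empty cluster: no consensus signature", call. = FALSE)
    return(NULL)
  }
  m <- rowMeans(members)
  if (sqrt(sum(m^2)) < 1e-12) {
    warning("degenerate consensus: member signatures cancel", call. = FALSE)
  }
  m
}

#' Percentile-thresholded signature network
#'
#' Computes all pairwise cosine distances between signatures and draws an
#' edge wherever the distance falls at or below the empirical
#' `q`-percentile of all pairwise distances (linear interpolation; ties at
#' the threshold are included). The global network of a screen uses
#' `q = 2`; per-cell-line networks use `q = 5`.
#'
#' @param vectors `G x n` matrix of signatures (`n >= 2`).
#' @param q percentile in (0, 100).
#' @param nodes optional data.frame of node attributes (one row per
#'   column of `vectors`).
#' @return a `signature_network` list: `nodes`, `edges` (data.frame
#'   `from`, `to`, `distance`), `threshold`, `q`.
#' @export
build_network <- function(vectors, q = 2, nodes = NULL) {
  vectors <- as.matrix(vectors)
  n <- ncol(vectors)
  if (n < 2) stop("need >= 2 signatures to build a network", call. = FALSE)
  ids <- colnames(vectors)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  D <- pairwise_cosine_distance(vectors, as_matrix = TRUE)
  lt <- which(lower.tri(D), arr.ind = TRUE)
  d <- D[lower.tri(D)]
  thr <- as.numeric(stats::quantile(d, q / 100, type = 7))
  sel <- d <= thr
  edges <- data.frame(from = ids[lt[sel, 2]], to = ids[lt[sel, 1]],
                      distance = d[sel], stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  else { nodes <- as.data.frame(nodes); nodes$id <- ids }
  structure(list(nodes = nodes, edges = edges, threshold = thr, q = q),
            class = "signature_network")
}

#' @export
print.signature_network <- function(x, ...) {
  cat(sprintf("signature_network: %d nodes, %d edges (cosine distance <= %.4g, lower %g%%)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold, x$q))
  invisible(x)
}

#' Export a network as SIF and tab-delimited edge/node tables
#'
#' @param network a [build_network()] result.
#' @param sif_path optional SIF output (`from  cd  to`).
#' @param edge_path optional tab-delimited edge list with distances.
#' @param node_path optional node-attribute CSV.
#' @return the network, invisibly.
#' @export
write_network <- function(network, sif_path = NULL, edge_path = NULL,
                          node_path = NULL) {
  stopifnot(inherits(network, "signature_network"))
  if (!is.null(sif_path)) {
    writeLines(paste(network$edges$from, "cd", network$edges$to, sep = "\t"),
               sif_path)
  }
  if (!is.null(edge_path)) {
    utils::write.table(network$edges, edge_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(node_path)) {
    utils::write.csv(network$nodes, node_path, row.names = FALSE)
  }
  invisible(network)
}

#' Cluster composition enrichment
#'
#' One-sided binomial test, per (cluster, category), of whether the
#' category is over-represented in the cluster relative to its global
#' frequency among all labeled conditions.
#'
#' @param assignment integer cluster ids (with `NA` for unassigned), as in
#'   [fuzzy_cluster()]`$assignment`.
#' @param labels category label per condition (same length); must be
#'   complete.
#' @return data.frame with `cluster`, `category`, `count`, `cluster_size`,
#'   `global_freq`, `p`.
#' @export
cluster_enrichment <- function(assignment, labels) {
  if (length(labels) != length(assignment)) {
    stop("labels and assignment lengths differ", call. = FALSE)
  }
  if (anyNA(labels)) stop("unlabeled condition(s) present", call. = FALSE)
  labels <- as.character(labels)
  global <- table(labels) / length(labels)
  assigned <- !is.na(assignment)
  out <- list()
  for (cl in sort(unique(assignment[assigned]))) {
    in_cl <- labels[assigned & assignment == cl]
    n <- length(in_cl)
    for (cat in names(global)) {
      x <- sum(in_cl == cat)
      p0 <- as.numeric(global[cat])
      # upper-tail P(X >= x) under Binomial(n, p0)
      p <- stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
      out[[length(out) + 1]] <- data.frame(
        cluster = cl, category = cat, count = x, cluster_size = n,
        global_freq = p0, p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, ~0 for independent ones. Items with `NA`
#' in either labeling are dropped.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("need >= 2 jointly labeled items", call. = FALSE)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(a), 2)
  expected <- ai * bj / nn
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (nij - expected) / (mx - expected)
}
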