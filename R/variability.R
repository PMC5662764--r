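#' Coefficient of variation of SCS across cell lines
#'
#' For each (drug, concentration) measured in at least two cell lines,
#' the sample CV (sd/mean, n-1 denominator) of the SCS across lines;
#' values are pooled per target class. Groups with non-positive mean SCS
#' are skipped with a flag.
#'
#' @param scs_table row-bound [batch_scs()] results with `cell_line`,
#'   `drug`, `concentration`, `target_class`, `SCS` (pre-filter to one
#'   time point, conventionally 24 h).
#' @return data.frame per (drug, concentration): `cv`, `n_lines`,
#'   `target_class`, `skipped`; class medians via [class_medians()].
#' @export
scs_cv <- function(scs_table) {
  key <- paste(scs_table$drug, signif(scs_table$concentration, 8), sep = "\r")
  rows <- lapply(split(seq_len(nrow(scs_table)), key), function(ix) {
    d <- scs_table[ix, ]
    if (length(unique(d$cell_line)) < 2) return(NULL)
    m <- mean(d$SCS)
    skipped <- m <= 0
    data.frame(drug = d$drug[1], concentration = d$concentration[1],
               target_class = d$target_class[1],
               cv = if (skipped) NA_real_ else stats::sd(d$SCS) / m,
               n_lines = length(unique(d$cell_line)), skipped = skipped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard deviation of GR_AOC across cell lines
#'
#' Per drug measured in at least two cell lines, the sample SD of GR_AOC
#' across lines, pooled per target class. Drugs in a single line are
#' skipped.
#'
#' @param profiles a [gr_profiles()] result with `cell_line`, `drug`,
#'   `target_class`, `GR_AOC`.
#' @return data.frame per drug: `sd`, `n_lines`, `target_class`.
#' @export
gr_aoc_sd <- function(profiles) {
  rows <- lapply(split(seq_len(nrow(profiles)), profiles$drug), function(ix) {
    d <- profiles[ix, ]
    if (length(unique(d$cell_line)) < 2) return(NULL)
    data.frame(drug = d$drug[1], target_class = d$target_class[1],
               sd = stats::sd(d$GR_AOC), n_lines = length(unique(d$cell_line)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-class medians of a variability statistic
#'
#' @param tab a [scs_cv()] or [gr_aoc_sd()] result.
#' @param value name of the statistic column (`"cv"` or `"sd"`).
#' @return data.frame `target_class`, `median`, `n`.
#' @export
class_medians <- function(tab, value = intersect(c("cv", "sd"), names(tab))[1]) {
  tab <- tab[!is.na(tab[[value]]), ]
  rows <- lapply(split(tab[[value]], tab$target_class), function(v) {
    data.frame(median = stats::median(v), n = length(v))
  })
  out <- do.call(rbind, rows)
  data.frame(target_class = names(rows), median = out$median, n = out$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dose-shift geometry of characteristic directions
#'
#' For every (cell line, drug) with signatures at both doses, the cosine
#' distance between its characteristic directions at `dose_low` and
#' `dose_high`, grouped by target class. A between-class baseline is
#' included: distances between the high-dose signatures of conditions
#' from different classes, the geometry expected for unrelated responses.
#'
#' @param cds a `cd_batch` or list of them (same time point).
#' @param dose_low,dose_high the two doses to compare (micromolar).
#' @return list: `shifts` (data.frame `cell_line`, `drug`,
#'   `target_class`, `distance`), `baseline` (numeric vector of
#'   between-class distances).
#' @export
dose_shift <- function(cds, dose_low, dose_high) {
  if (inherits(cds, "cd_batch")) cds <- list(cds)
  vectors <- do.call(cbind, lapply(cds, `[[`, "vectors"))
  conditions <- do.call(rbind, lapply(cds, `[[`, "conditions"))
  is_lo <- abs(conditions$concentration - dose_low) < 1e-8 * max(1, dose_low)
  is_hi <- abs(conditions$concentration - dose_high) < 1e-8 * max(1, dose_high)
  key <- paste(conditions$cell_line, conditions$drug, sep = "\r")
  rows <- list()
  for (k in unique(key[is_lo])) {
    lo <- which(is_lo & key == k)
    hi <- which(is_hi & key == k)
    if (length(lo) != 1 || length(hi) != 1) next  # dose missing: skip
    rows[[length(rows) + 1L]] <- data.frame(
      cell_line = conditions$cell_line[lo], drug = conditions$drug[lo],
      target_class = conditions$target_class[lo],
      distance = cosine_distance(vectors[, lo], vectors[, hi]),
      stringsAsFactors = FALSE)
  }
  shifts <- do.call(rbind, rows)
  hi_ix <- which(is_hi & !is.na(conditions$target_class))
  baseline <- numeric(0)
  if (length(hi_ix) >= 2) {
    D <- pairwise_cosine_distance(vectors[, hi_ix, drop = FALSE], as_matrix = TRUE)
    cls <- conditions$target_class[hi_ix]
    diff_class <- outer(cls, cls, "!=") & lower.tri(D)
    baseline <- D[diff_class]
  }
  list(shifts = shifts, baseline = baseline)
}

#' Cross-cell-line variability of an abundance table
#'
#' For each entity (protein, phospho-peptide, ...) the sample SD of
#' log10 abundance across cell lines, with a rank-sum (Mann-Whitney)
#' test between two named entity groups.
#'
#' @param abundance entity x cell-line matrix of positive values.
#' @param groups character vector (named by entity or in row order)
#'   assigning each entity to a group (e.g. pathway).
#' @param test_pair length-2 character: the two groups to compare
#'   (default: the two most frequent).
#' @return list: `sds` (data.frame `entity`, `group`, `sd`), `test`
#'   (`groups`, `p`, statistic `W`).
#' @export
cross_line_sd <- function(abundance, groups, test_pair = NULL) {
  abundance <- as.matrix(abundance)
  if (any(abundance <= 0)) stop("abundances must be positive", call. = FALSE)
  if (ncol(abundance) < 2) stop("need >= 2 cell lines", call. = FALSE)
  if (length(groups) != nrow(abundance)) {
    stop("one group per entity required", call. = FALSE)
  }
  sds <- apply(log10(abundance), 1, stats::sd)
  ent <- rownames(abundance)
  if (is.null(ent)) ent <- as.character(seq_along(sds))
  out <- data.frame(entity = ent, group = as.character(groups), sd = sds,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(test_pair)) {
    test_pair <- names(sort(table(out$group), decreasing = TRUE))[1:2]
  }
  a <- out$sd[out$group == test_pair[1]]
  b <- out$sd[out$group == test_pair[2]]
  wt <- stats::wilcox.test(a, b, exact = FALSE)
  list(sds = out,
       test = list(groups = test_pair, W = unname(wt$statistic),
                   p = wt$p.value))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and an asymptotic t
#' p-value. Constant input is flagged (`rho = NA`).
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @return list: `rho`, `p`, `n`, `flag` (`"ok"` or `"constant_input"`).
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = "constant_input"))
  }
  rx <- rank(x); ry <- rank(y)  # average ranks for ties
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n,
       flag = "ok")
}
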