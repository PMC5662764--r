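#' Classify a perturbation into response classes I-IV
#'
#' Quadrants of the (GR, SCS) plane at the fixed cutoffs `GR = 0.66`
#' (phenotypic response below the cutoff counts as responsive) and
#' `SCS = 1.3` (molecular response above the cutoff counts as consistent):
#'
#' * **I** — `GR >= gr_cut` and `SCS <= scs_cut`: non-responsive by both
#'   measures (resistance).
#' * **II** — `GR < gr_cut` and `SCS > scs_cut`: responsive by both
#'   (sensitivity).
#' * **III** — `GR < gr_cut` and `SCS <= scs_cut`: phenotypic response
#'   without a consistent transcriptional signature.
#' * **IV** — `GR >= gr_cut` and `SCS > scs_cut`: consistent
#'   transcriptional response without growth inhibition (adaptive
#'   resistance / synergy candidates).
#'
#' Values exactly at a cutoff fall on the non-responsive (I/IV for GR,
#' I/III for SCS) side, generalizing the strict `SCS > 1.3` filter.
#'
#' @param GR,SCS finite numeric vectors (recycled to common length).
#' @param gr_cut,scs_cut quadrant cutoffs (defaults 0.66 and 1.3).
#' @return factor with levels `I`, `II`, `III`, `IV`.
#' @export
classify_response <- function(GR, SCS, gr_cut = 0.66, scs_cut = 1.3) {
  n <- max(length(GR), length(SCS))
  GR <- rep_len(GR, n); SCS <- rep_len(SCS, n)
  if (!all(is.finite(GR)) || !all(is.finite(SCS))) {
    stop("GR and SCS must be finite", call. = FALSE)
  }
  gr_resp <- GR < gr_cut
  scs_resp <- SCS > scs_cut
  cls <- ifelse(!gr_resp & !scs_resp, "I",
         ifelse(gr_resp & scs_resp, "II",
         ifelse(gr_resp & !scs_resp, "III", "IV")))
  factor(cls, levels = c("I", "II", "III", "IV"))
}

#' Pair molecular and phenotypic responses of the same perturbations
#'
#' Joins an SCS table (expression arm, typically the 24 h batches) with a
#' per-dose GR table (count arm, 72 h) on exact (cell line, drug,
#' concentration) match; unmatched rows are skipped with a warning.
#'
#' @param scs_table a [batch_scs()] result (or row-bound results), with
#'   `cell_line`, `drug`, `concentration`, `SCS`.
#' @param gr_table a [gr_table()] result with `cell_line`, `drug`,
#'   `concentration`, `GR`.
#' @param time_h expression time point to use (default 24; ignored when
#'   the SCS table has no `time_h` column).
#' @return data.frame with the join keys, `GR_used`, `SCS_used`, and
#'   `class` from [classify_response()].
#' @export
pair_responses <- function(scs_table, gr_table, time_h = 24) {
  s <- scs_table
  if (!is.null(s$time_h)) s <- s[s$time_h == time_h, ]
  key_s <- paste(s$cell_line, s$drug, signif(s$concentration, 8), sep = "\r")
  key_g <- paste(gr_table$cell_line, gr_table$drug,
                 signif(gr_table$concentration, 8), sep = "\r")
  m <- match(key_s, key_g)
  if (anyNA(m)) {
    warning(sprintf("%d condition(s) without a matching GR measurement skipped",
                    sum(is.na(m))), call. = FALSE)
  }
  keep <- which(!is.na(m))
  out <- data.frame(
    cell_line = s$cell_line[keep], drug = s$drug[keep],
    concentration = s$concentration[keep],
    target_class = if (is.null(s$target_class))
                     rep(NA_character_, length(keep))
                   else s$target_class[keep],
    GR_used = gr_table$GR[m[keep]], SCS_used = s$SCS[keep],
    stringsAsFactors = FALSE)
  out$class <- classify_response(out$GR_used, out$SCS_used)
  out
}

#' Per-group response-class fractions
#'
#' @param classifications a data.frame with a `class` factor (as from
#'   [pair_responses()]) and the grouping column.
#' @param group_by name of the grouping column (e.g. `"cell_line"` or
#'   `"target_class"`), or `NULL` for overall fractions.
#' @return data.frame of per-group fractions over classes I-IV (rows sum
#'   to 1 per group).
#' @export
class_fractions <- function(classifications, group_by = NULL) {
  if (nrow(classifications) == 0) stop("no classifications", call. = FALSE)
  cls <- factor(classifications$class, levels = c("I", "II", "III", "IV"))
  grp <- if (is.null(group_by)) rep("all", length(cls))
         else classifications[[group_by]]
  if (is.null(grp)) stop("unknown grouping column: ", group_by, call. = FALSE)
  tab <- table(group = grp, class = cls)
  if (any(rowSums(tab) == 0)) stop("empty group", call. = FALSE)
  frac <- sweep(tab, 1, rowSums(tab), "/")
  out <- as.data.frame.matrix(frac)
  out <- cbind(data.frame(group = rownames(out), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
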