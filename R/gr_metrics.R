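#' 50%-trimmed mean of day-0 counts
#'
#' Discards the lowest 25% and highest 25% of the day-0 untreated counts
#' (`floor(n/4)` values from each end) and averages the rest; the robust
#' baseline `x_0` of the GR computation.
#'
#' @param counts numeric vector of day-0 viable-cell counts (all `>= 0`).
#' @return scalar trimmed mean.
#' @export
trimmed_mean_day0 <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("no day-0 counts", call. = FALSE)
  if (any(counts < 0)) stop("negative day-0 count", call. = FALSE)
  k <- floor(length(counts) / 4)
  s <- sort(counts)
  mean(s[(k + 1):(length(s) - k)])
}

#' Normalized growth-rate inhibition (GR)
#'
#' `GR(c) = 2 ^ [ log2(x_c / x_0) / log2(x_ctrl / x_0) ] - 1`, the ratio
#' of growth rates under drug and under vehicle, mapped so that 1 means
#' growth at the untreated rate, 0 complete cytostasis, and negative
#' values cytotoxicity. Unlike relative viability, GR is insensitive to
#' division rate and plating density, because both numerator and
#' denominator are growth rates measured against the same day-0 baseline.
#'
#' @param x_c treated viable-cell count(s) at the endpoint.
#' @param x_ctrl same-plate vehicle-control count (mean over control
#'   wells).
#' @param x_0 day-0 baseline, from [trimmed_mean_day0()].
#' @return GR value(s); vectorized over `x_c`.
#' @export
gr_value <- function(x_c, x_ctrl, x_0) {
  if (any(c(x_c, x_ctrl, x_0) <= 0)) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (length(x_ctrl) != 1 || length(x_0) != 1) {
    stop("x_ctrl and x_0 must be scalars", call. = FALSE)
  }
  denom <- log2(x_ctrl / x_0)
  if (abs(denom) < 1e-12) {
    stop("undefined normalization: control count equals the day-0 baseline",
         call. = FALSE)
  }
  2^(log2(x_c / x_0) / denom) - 1
}

#' GR area over the curve
#'
#' `GR_AOC = mean(1 - GR)` over the tested doses: 0 for no response at any
#' dose, 1 for complete cytostasis everywhere, above 1 with cytotoxicity.
#' The plain mean coincides with trapezoidal integration over log-dose for
#' the uniform dilution series used in these screens.
#'
#' @param gr numeric vector of per-dose GR values (`>= 2` doses).
#' @return scalar GR_AOC.
#' @export
gr_aoc <- function(gr) {
  if (length(gr) < 2) stop("GR_AOC needs >= 2 doses", call. = FALSE)
  mean(1 - gr)
}

#' Fit a sigmoidal GR dose-response curve
#'
#' Least-squares fit of
#' `GR(c) = GR_inf + (1 - GR_inf) / (1 + (c / GEC50)^hill)`
#' with bounds `GR_inf` in `[-1, 1]`, `GEC50` within the tested range
#' scaled by `[0.01, 100]`, `hill` in `[0.1, 5]`, from a multi-start
#' L-BFGS-B (GEC50 started at every tested dose, hill at 1 and 2). If the
#' sigmoid does not beat a flat line by an F-test at `alpha = 0.05` (or no
#' start converges), a flat fit at the mean GR is returned with
#' `flat = TRUE`.
#'
#' @param doses dose series in micromolar (`>= 4` doses, positive).
#' @param gr GR value per dose.
#' @param alpha significance level of the flat-line F-test.
#' @return list: `GR_inf`, `GEC50`, `hill`, `rss`, `flat`, `converged`.
#' @export
fit_gr_curve <- function(doses, gr, alpha = 0.05) {
  stopifnot(length(doses) == length(gr))
  if (length(doses) < 4) stop("curve fitting needs >= 4 doses", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  o <- order(doses)
  doses <- doses[o]; gr <- gr[o]
  n <- length(doses)

  flat_rss <- sum((gr - mean(gr))^2)
  flat <- list(GR_inf = mean(gr), GEC50 = NA_real_, hill = NA_real_,
               rss = flat_rss, flat = TRUE, converged = TRUE)

  lg_lo <- log10(min(doses) * 0.01); lg_hi <- log10(max(doses) * 100)
  obj <- function(par) {
    pred <- par[1] + (1 - par[1]) / (1 + (doses / 10^par[2])^par[3])
    sum((pred - gr)^2)
  }
  best <- NULL
  for (c0 in doses) for (h0 in c(1, 2)) {
    fit <- tryCatch(
      stats::optim(c(min(max(gr[n], -1), 1), log10(c0), h0), obj,
                   method = "L-BFGS-B",
                   lower = c(-1, lg_lo, 0.1), upper = c(1, lg_hi, 5),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(flat)

  rss1 <- best$value
  df1 <- n - 3; df0 <- n - 1
  keep <- FALSE
  if (df1 > 0 && flat_rss > 1e-12) {  # a perfect flat line is never beaten
    if (rss1 < 1e-12 * flat_rss) keep <- TRUE  # numerically exact fit
    else {
      Fstat <- ((flat_rss - rss1) / (df0 - df1)) / (rss1 / df1)
      keep <- stats::pf(Fstat, df0 - df1, df1, lower.tail = FALSE) < alpha
    }
  }
  if (!keep) return(flat)
  list(GR_inf = best$par[1], GEC50 = 10^best$par[2], hill = best$par[3],
       rss = rss1, flat = FALSE, converged = best$convergence == 0)
}

#' Per-condition GR values from a count table
#'
#' Converts a long count table (see [simulate_counts()] for the layout:
#' one row per well with `cell_line`, `drug`, `concentration`, `time_h`,
#' `plate_id`, `replicate`, `count`; vehicle wells named [VEHICLE]; day-0
#' wells at `time_h = 0`) into GR values. Per plate, the control reference
#' is the mean vehicle count on that plate and the baseline is the
#' 50%-trimmed mean of the cell line's day-0 plate; technical plate
#' replicates are then averaged per condition.
#'
#' @param counts a count `data.frame` as above.
#' @return data.frame with one row per (cell_line, drug, concentration):
#'   `GR` (technical-replicate mean), `n_plates`, plus `target_class` if
#'   present in the input.
#' @export
gr_table <- function(counts) {
  req <- c("cell_line", "drug", "concentration", "time_h", "plate_id", "count")
  miss <- setdiff(req, names(counts))
  if (length(miss) > 0) stop("count table missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (any(counts$count < 0)) stop("negative cell count", call. = FALSE)
  day0 <- counts[counts$time_h == 0, ]
  endp <- counts[counts$time_h > 0, ]
  veh <- is_vehicle_well(endp)
  x0 <- vapply(split(day0$count, day0$cell_line), trimmed_mean_day0, numeric(1))

  trt <- endp[!veh, ]
  ctrl_by_plate <- vapply(split(endp$count[veh], endp$plate_id[veh]),
                          mean, numeric(1))
  missing_ctrl <- setdiff(unique(trt$plate_id), names(ctrl_by_plate))
  if (length(missing_ctrl) > 0) {
    stop("treated plate(s) without vehicle controls: ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  }
  if (!all(trt$cell_line %in% names(x0))) {
    stop("cell line(s) without a day-0 plate: ",
         paste(setdiff(unique(trt$cell_line), names(x0)), collapse = ", "),
         call. = FALSE)
  }
  trt$GR <- NA_real_
  for (p in unique(trt$plate_id)) {
    ix <- trt$plate_id == p
    cl <- trt$cell_line[ix][1]
    trt$GR[ix] <- gr_value(trt$count[ix], ctrl_by_plate[[p]], x0[[cl]])
  }
  key <- paste(trt$cell_line, trt$drug, trt$concentration, sep = "\r")
  agg <- lapply(split(seq_len(nrow(trt)), key), function(ix) {
    data.frame(cell_line = trt$cell_line[ix[1]], drug = trt$drug[ix[1]],
               concentration = trt$concentration[ix[1]],
               target_class = if (is.null(trt$target_class)) NA_character_
                              else trt$target_class[ix[1]],
               GR = mean(trt$GR[ix]), n_plates = length(ix),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$cell_line, out$drug, out$concentration), ]
}

#' Dose-response profiles with GR_AOC and optional curve fit
#'
#' Summarizes a [gr_table()] result per (cell line, drug): the ordered
#' dose series, GR_AOC, and (when `fit = TRUE` and >= 4 doses) the fitted
#' sigmoid parameters.
#'
#' @param grt a [gr_table()] data.frame.
#' @param fit whether to fit [fit_gr_curve()] per profile.
#' @return data.frame with one row per (cell_line, drug): `GR_AOC`,
#'   `n_doses`, `GR_inf`, `GEC50`, `hill`, `flat`, and (descriptive)
#'   `GR_max`, the GR at the highest tested dose.
#' @export
gr_profiles <- function(grt, fit = TRUE) {
  key <- paste(grt$cell_line, grt$drug, sep = "\r")
  rows <- lapply(split(seq_len(nrow(grt)), key), function(ix) {
    d <- grt[ix, ]
    d <- d[order(d$concentration), ]
    ft <- if (fit && nrow(d) >= 4) fit_gr_curve(d$concentration, d$GR)
          else list(GR_inf = NA_real_, GEC50 = NA_real_, hill = NA_real_,
                    flat = NA)
    data.frame(cell_line = d$cell_line[1], drug = d$drug[1],
               target_class = d$target_class[1],
               GR_AOC = gr_aoc(d$GR), n_doses = nrow(d),
               GR_max = d$GR[nrow(d)],
               GR_inf = ft$GR_inf, GEC50 = ft$GEC50, hill = ft$hill,
               flat = ft$flat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
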