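#' Excess over Bliss independence on the GR scale
#'
#' `EOB_GR = (1 - GR_AB) - (1 - GR_A) - (1 - GR_B) + (1 - GR_A)(1 - GR_B)`.
#' On the `(1 - GR)` effect scale this is exactly the observed combined
#' effect minus the Bliss prediction
#' `E_A + E_B - E_A * E_B`; positive values indicate synergy, negative
#' antagonism. GR values above 1 (super-growth) are allowed; the effect
#' scale simply goes negative.
#'
#' @param gr_a,gr_b single-agent GR values at the combination's doses.
#' @param gr_ab combination GR value.
#' @return EOB_GR value(s); vectorized and symmetric in A and B.
#' @export
eob_gr <- function(gr_a, gr_b, gr_ab) {
  if (!all(is.finite(c(gr_a, gr_b, gr_ab)))) {
    stop("GR values must be finite", call. = FALSE)
  }
  (1 - gr_ab) - (1 - gr_a) - (1 - gr_b) + (1 - gr_a) * (1 - gr_b)
}

#' Excess over Bliss across a checkerboard
#'
#' Applies [eob_gr()] element-wise over a dose-pair grid, pulling each
#' cell's single-agent GR values from the grid's own margins (rows with
#' one dose equal to zero). Margin cells get `EOB = 0` by construction
#' (a single agent is its own Bliss prediction).
#'
#' @param grid long data.frame for one replicate: `conc_a`, `conc_b`,
#'   `GR`. Must contain the margin rows covering every dose level used in
#'   interior cells.
#' @return the grid with an `EOB` column (the `(0, 0)` cell, if present,
#'   is kept with `EOB = 0`).
#' @export
checkerboard_eob <- function(grid) {
  req <- c("conc_a", "conc_b", "GR")
  if (!all(req %in% names(grid))) {
    stop("grid needs columns conc_a, conc_b, GR", call. = FALSE)
  }
  ma <- grid[grid$conc_b == 0 & grid$conc_a > 0, ]
  mb <- grid[grid$conc_a == 0 & grid$conc_b > 0, ]
  gr_margin <- function(margin, conc, which) {
    m <- match(signif(conc, 8), signif(margin[[which]], 8))
    if (anyNA(m[conc > 0])) {
      stop("missing single-agent margin for dose(s): ",
           paste(unique(conc[conc > 0 & is.na(m)]), collapse = ", "),
           call. = FALSE)
    }
    ifelse(conc == 0, 1, margin$GR[m])
  }
  gr_a <- gr_margin(ma, grid$conc_a, "conc_a")
  gr_b <- gr_margin(mb, grid$conc_b, "conc_b")
  grid$EOB <- eob_gr(gr_a, gr_b, grid$GR)
  grid
}

#' Per-replicate GR grids from a combination count table
#'
#' Converts [simulate_combo()] counts (or any table in that layout) to GR
#' values per biological replicate: each replicate's control reference is
#' the mean of its own vehicle wells (`conc_a = conc_b = 0` at the
#' endpoint) and its baseline the 50%-trimmed mean of its day-0 wells.
#'
#' @param combo_counts long data.frame with `conc_a`, `conc_b`, `time_h`,
#'   `replicate`, `count`.
#' @return data.frame `replicate`, `conc_a`, `conc_b`, `GR` (the control
#'   cell is carried with `GR = 1`).
#' @export
combo_gr <- function(combo_counts) {
  rows <- lapply(split(combo_counts, combo_counts$replicate), function(d) {
    day0 <- d$count[d$time_h == 0]
    e <- d[d$time_h > 0, ]
    ctrl <- e$count[e$conc_a == 0 & e$conc_b == 0]
    if (length(day0) == 0 || length(ctrl) == 0) {
      stop("replicate without day-0 or control wells", call. = FALSE)
    }
    x0 <- trimmed_mean_day0(day0)
    x_ctrl <- mean(ctrl)
    trt <- e[e$conc_a > 0 | e$conc_b > 0, ]
    agg <- stats::aggregate(count ~ conc_a + conc_b, trt, mean)
    data.frame(replicate = d$replicate[1], conc_a = c(0, agg$conc_a),
               conc_b = c(0, agg$conc_b),
               GR = c(1, gr_value(agg$count, x_ctrl, x0)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sample test of excess over Bliss
#'
#' Two-sided one-sample t-test of per-replicate EOB values against zero,
#' reported as mean, standard error, and p-value. With zero variance
#' across replicates the t statistic is undefined; `p = 1` is reported
#' with the `zero_variance` flag. With a single replicate no test is run
#' (`p = NA`, flag `no_test`).
#'
#' @param eob numeric vector of per-replicate EOB values.
#' @return list: `mean`, `se`, `p`, `n`, `flag` (`"ok"`,
#'   `"zero_variance"`, or `"no_test"`).
#' @export
synergy_test <- function(eob) {
  n <- length(eob)
  if (n < 1) stop("no EOB values", call. = FALSE)
  m <- mean(eob)
  if (n < 2) {
    return(list(mean = m, se = NA_real_, p = NA_real_, n = n, flag = "no_test"))
  }
  s <- stats::sd(eob)
  se <- s / sqrt(n)
  if (s < 1e-15) {
    return(list(mean = m, se = 0, p = 1, n = n, flag = "zero_variance"))
  }
  tstat <- m / se
  list(mean = m, se = se, p = 2 * stats::pt(-abs(tstat), df = n - 1),
       n = n, flag = "ok")
}

#' Replicate-level synergy over a checkerboard
#'
#' Computes per-replicate EOB grids ([checkerboard_eob()] within each
#' replicate) and then, per interior dose pair, the across-replicate
#' [synergy_test()].
#'
#' @param gr_long a [combo_gr()] result (columns `replicate`, `conc_a`,
#'   `conc_b`, `GR`).
#' @return data.frame per dose pair with `conc_a`, `conc_b`, `EOB`
#'   (mean), `se`, `p`, `n`.
#' @export
combo_synergy <- function(gr_long) {
  eobs <- do.call(rbind, lapply(split(gr_long, gr_long$replicate),
                                checkerboard_eob))
  interior <- eobs[eobs$conc_a > 0 & eobs$conc_b > 0, ]
  rows <- lapply(split(interior, paste(interior$conc_a, interior$conc_b)),
                 function(d) {
    st <- synergy_test(d$EOB)
    data.frame(conc_a = d$conc_a[1], conc_b = d$conc_b[1], EOB = st$mean,
               se = st$se, p = st$p, n = st$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$conc_a, out$conc_b), ]
}
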