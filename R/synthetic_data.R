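#' Configuration of the synthetic screen generator
#'
#' Describes a synthetic perturbational screen mirroring the design the
#' analysis pipeline assumes: a panel of cell lines exposed to a drug
#' panel at a 6-point dose series spanning a ~250-fold range (3.33-fold
#' dilutions from 10 uM), profiled for 978 landmark genes at 3 and 24 h
#' on `J = 3` replicate plates carrying their own vehicle controls, and
#' counted at day 0 and 72 h for GR metrics.
#'
#' Drugs are grouped into target classes. A `shared_fraction` of classes
#' is "universal": all cell lines respond along one planted direction per
#' time point, with the same amplitude in every line. The rest are
#' cell-line "specific": each cell line gets its own planted direction,
#' and the response amplitude is additionally scaled by a per-(drug, cell
#' line) sensitivity factor drawn uniformly from `sensitivity_range` —
#' emulating signaling-kinase inhibitors, whose responses are dominated
#' by one or two lines while other lines barely respond (hence the
#' default range reaches down to 0.1, near-non-responders). Optionally, `rotation_classes` classes
#' (taken from the universal ones) rotate their direction with dose
#' between two orthogonal endpoints, emulating off-target behavior of
#' RTK/ECM inhibitors at high dose.
#'
#' The signal amplitude follows a saturating dose link
#' `amplitude(c) = effect_size * sensitivity * c^amp_h / (c^amp_h + amp_K^amp_h)`.
#' Expression noise is additive Gaussian per gene; count noise is
#' multiplicative log-normal; plate effects are additive per-plate scalars
#' removed implicitly by same-plate control comparison.
#'
#' @param n_genes number of landmark genes (default 978).
#' @param n_cell_lines,n_drugs,n_classes panel sizes (defaults 6, 100, 10).
#' @param doses dose series in micromolar, strictly increasing (default
#'   3.33-fold dilutions from 10 uM, 243-fold range).
#' @param time_points expression time points in hours (default `c(3, 24)`).
#' @param J replicate plates per batch (default 3).
#' @param N vehicle-control wells per plate (default 8).
#' @param effect_size signal amplitude scale (default 5; amplitudes at
#'   the top dose are then ~10x the per-gene noise).
#' @param shared_fraction fraction of classes with a universal direction
#'   (default 0.5).
#' @param rotation_classes number of universal classes whose direction
#'   rotates with dose (default 0).
#' @param noise_sd per-gene expression noise SD (default 0.5).
#' @param baseline_mean,baseline_sd per-(gene, cell line) baseline
#'   expression distribution (defaults 6, 1, on the normalized log-like
#'   scale of level-3 data).
#' @param plate_effect_sd SD of the additive per-plate scalar (default 1).
#' @param amp_K,amp_h dose-amplitude link parameters (defaults 1 uM, 1).
#' @param sensitivity_range range of the per-(drug, cell line)
#'   sensitivity factor applied to specific-class drugs (default
#'   `c(0.1, 1.9)`: mean 1, so effect sizes stay matched to universal
#'   classes, with near-non-responding lines included).
#' @param day0_count expected day-0 viable-cell count (default 1000).
#' @param n_day0_wells wells on the day-0 plate (default 12).
#' @param doubling_range cell-line doubling-time range in hours, drawn
#'   once per line (default `c(24, 48)`).
#' @param duration_h count endpoint in hours (default 72).
#' @param count_noise_sd log-normal count noise SD (default 0.05).
#' @param gr_params optional data.frame (`drug`, `cell_line`, `GR_inf`,
#'   `GEC50`, `hill`) of planted dose-response parameters; drawn randomly
#'   when `NULL`.
#' @param seed integer master seed (default 1); all generators are
#'   deterministic given it.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 978, n_cell_lines = 6, n_drugs = 100,
                              n_classes = 10,
                              doses = 10 / 3^(5:0),
                              time_points = c(3, 24), J = 3, N = 8,
                              effect_size = 5, shared_fraction = 0.5,
                              rotation_classes = 0,
                              noise_sd = 0.5, baseline_mean = 6,
                              baseline_sd = 1, plate_effect_sd = 1,
                              amp_K = 1, amp_h = 1,
                              sensitivity_range = c(0.1, 1.9),
                              day0_count = 1000, n_day0_wells = 12,
                              doubling_range = c(24, 48), duration_h = 72,
                              count_noise_sd = 0.05, gr_params = NULL,
                              seed = 1) {
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (day0_count <= 0) stop("day0_count must be positive", call. = FALSE)
  stopifnot(J >= 1, N >= 2, n_genes >= 2, n_classes >= 1,
            rotation_classes >= 0)
  cfg <- as.list(environment())
  cfg$n_universal <- round(shared_fraction * n_classes)
  cfg$rotation_classes <- min(rotation_classes, cfg$n_universal)
  structure(cfg, class = "simulation_config")
}

random_unit <- function(G) {
  v <- stats::rnorm(G)
  v / sqrt(sum(v^2))
}

# class/drug bookkeeping shared by the generators
sim_panel <- function(config) {
  classes <- sprintf("class%02d", seq_len(config$n_classes))
  type <- rep("specific", config$n_classes)
  if (config$n_universal > 0) type[seq_len(config$n_universal)] <- "universal"
  if (config$rotation_classes > 0) type[seq_len(config$rotation_classes)] <- "rotation"
  names(type) <- classes
  drugs <- sprintf("drug%03d", seq_len(config$n_drugs))
  drug_class <- classes[(seq_len(config$n_drugs) - 1) %% config$n_classes + 1]
  names(drug_class) <- drugs
  lines <- sprintf("line%02d", seq_len(config$n_cell_lines))
  list(classes = classes, class_type = type, drugs = drugs,
       drug_class = drug_class, lines = lines)
}

#' Simulate an expression screen with planted ground truth
#'
#' Generates level-3-like landmark expression for every (cell line, time
#' point) batch of the design in [simulation_config()]: per well,
#' `value = baseline(gene, cell line) + plate_effect + amplitude(dose) *
#' planted_direction + N(0, noise_sd)`, with `N` vehicle-control wells per
#' plate receiving baseline + plate effect + noise only.
#'
#' @param config a [simulation_config()].
#' @return list with `expression` (a `SummarizedExperiment` with well
#'   metadata, ready for [assemble_batches()]) and `truth` (planted
#'   directions keyed by `class|time|cell-line-or-*`, per-condition truth
#'   table with `cluster_label` and planted `amplitude`, class types,
#'   sensitivities, and the config).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- sim_panel(config)
  G <- config$n_genes
  nd <- length(config$doses)

  with_seed(config$seed, {
    baseline <- matrix(stats::rnorm(G * config$n_cell_lines,
                                    config$baseline_mean, config$baseline_sd),
                       G, config$n_cell_lines, dimnames = list(NULL, panel$lines))
    sens <- matrix(1, config$n_drugs, config$n_cell_lines,
                   dimnames = list(panel$drugs, panel$lines))
    for (dr in panel$drugs) {
      if (panel$class_type[[panel$drug_class[[dr]]]] == "specific") {
        sens[dr, ] <- stats::runif(config$n_cell_lines,
                                   config$sensitivity_range[1],
                                   config$sensitivity_range[2])
      }
    }
    directions <- list()
    for (cl in panel$classes) for (th in config$time_points) {
      ty <- panel$class_type[[cl]]
      if (ty == "universal") {
        directions[[paste(cl, th, "*", sep = "|")]] <- random_unit(G)
      } else if (ty == "rotation") {
        d0 <- random_unit(G)
        d1 <- random_unit(G)
        d1 <- d1 - sum(d1 * d0) * d0
        d1 <- d1 / sqrt(sum(d1^2))
        directions[[paste(cl, th, "*", "lo", sep = "|")]] <- d0
        directions[[paste(cl, th, "*", "hi", sep = "|")]] <- d1
      } else {
        for (ln in panel$lines) {
          directions[[paste(cl, th, ln, sep = "|")]] <- random_unit(G)
        }
      }
    }

    n_per_plate <- config$N + config$n_drugs * nd
    n_wells <- config$n_cell_lines * length(config$time_points) * config$J * n_per_plate
    values <- matrix(NA_real_, G, n_wells)
    meta <- vector("list", config$n_cell_lines * length(config$time_points) * config$J)
    truth_rows <- list()
    w <- 0L; b <- 0L
    for (ln in panel$lines) for (th in config$time_points) {
      for (j in seq_len(config$J)) {
        b <- b + 1L
        plate <- paste(ln, th, "P", j, sep = "_")
        pe <- stats::rnorm(1, 0, config$plate_effect_sd)
        # controls
        for (k in seq_len(config$N)) {
          w <- w + 1L
          values[, w] <- baseline[, ln] + pe + stats::rnorm(G, 0, config$noise_sd)
        }
        # treated wells
        for (dr in panel$drugs) {
          cl <- panel$drug_class[[dr]]
          ty <- panel$class_type[[cl]]
          for (di in seq_len(nd)) {
            dose <- config$doses[di]
            amp <- config$effect_size * sens[dr, ln] *
              dose^config$amp_h / (dose^config$amp_h + config$amp_K^config$amp_h)
            dir <- sim_direction(directions, cl, th, ln, ty, di, nd)
            w <- w + 1L
            values[, w] <- baseline[, ln] + pe + amp * dir +
              stats::rnorm(G, 0, config$noise_sd)
            if (j == 1L) {
              truth_rows[[length(truth_rows) + 1L]] <- data.frame(
                cell_line = ln, drug = dr, concentration = dose, time_h = th,
                class = cl, class_type = ty,
                cluster_label = if (ty == "specific") paste(cl, th, ln, sep = "|")
                                else paste(cl, th, sep = "|"),
                direction_key = sim_direction_key(cl, th, ln, ty),
                amplitude = amp, stringsAsFactors = FALSE)
            }
          }
        }
        meta[[b]] <- data.frame(
          plate_id = plate,
          well = sprintf("%s_w%03d", plate, seq_len(n_per_plate)),
          cell_line = ln,
          drug = c(rep(VEHICLE, config$N), rep(panel$drugs, each = nd)),
          concentration = c(rep(0, config$N), rep(config$doses, config$n_drugs)),
          time_h = th,
          replicate = c(seq_len(config$N), rep(j, config$n_drugs * nd)),
          target_class = c(rep(NA_character_, config$N),
                           rep(unname(panel$drug_class), each = nd)),
          stringsAsFactors = FALSE)
      }
    }
    wells <- do.call(rbind, meta)
    rownames(values) <- sprintf("gene%04d", seq_len(G))
    colnames(values) <- wells$well
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = values),
      colData = S4Vectors::DataFrame(wells, row.names = wells$well))
    truth_tab <- do.call(rbind, truth_rows)
    truth_tab$condition_key <- condition_key(truth_tab)
    list(expression = se,
         truth = list(directions = directions, condition_truth = truth_tab,
                      drug_class = panel$drug_class,
                      class_type = panel$class_type,
                      sensitivity = sens, baseline = baseline,
                      config = config))
  })
}

sim_direction_key <- function(cl, th, ln, ty) {
  switch(ty,
         universal = paste(cl, th, "*", sep = "|"),
         rotation = paste(cl, th, "*", "hi", sep = "|"),
         paste(cl, th, ln, sep = "|"))
}

sim_direction <- function(directions, cl, th, ln, ty, dose_index, n_doses) {
  if (ty == "universal") return(directions[[paste(cl, th, "*", sep = "|")]])
  if (ty == "specific") return(directions[[paste(cl, th, ln, sep = "|")]])
  # rotation: interpolate between the low- and high-dose endpoints
  t <- if (n_doses > 1) (dose_index - 1) / (n_doses - 1) else 1
  d <- (1 - t) * directions[[paste(cl, th, "*", "lo", sep = "|")]] +
    t * directions[[paste(cl, th, "*", "hi", sep = "|")]]
  d / sqrt(sum(d^2))
}

# planted GR curve
gr_curve <- function(c, GR_inf, GEC50, hill) {
  GR_inf + (1 - GR_inf) / (1 + (c / GEC50)^hill)
}

# invert GR back to a treated count given true control and day-0 counts
count_from_gr <- function(gr, x_ctrl, x_0) {
  gr <- pmax(gr, -1 + 1e-9)
  x_0 * 2^(log2(gr + 1) * log2(x_ctrl / x_0))
}

draw_gr_params <- function(config, drugs, lines) {
  grid <- expand.grid(drug = drugs, cell_line = lines,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  lo <- log10(min(config$doses) * 3); hi <- log10(max(config$doses) / 3)
  grid$GR_inf <- stats::runif(n, -0.6, 0.8)
  grid$GEC50 <- 10^stats::runif(n, lo, hi)
  grid$hill <- stats::runif(n, 1, 3)
  grid
}

#' Simulate viable-cell count tables
#'
#' Generates day-0, vehicle-control, and drug-treated counts for the
#' design in [simulation_config()]. Vehicle wells grow exponentially from
#' the day-0 count at a per-line division rate (doubling time drawn once
#' per line from `doubling_range`); treated counts satisfy the planted GR
#' dose-response `GR(c) = GR_inf + (1 - GR_inf) / (1 + (c/GEC50)^hill)`
#' exactly before multiplicative log-normal noise.
#'
#' @param config a [simulation_config()]; `config$gr_params` may carry
#'   explicit planted curve parameters, otherwise they are drawn.
#' @return list with `counts` (long data.frame: one row per well with
#'   `cell_line`, `drug`, `concentration`, `time_h` (0 or `duration_h`),
#'   `plate_id`, `well`, `replicate`, `target_class`, `count`) and
#'   `truth` (`gr_params`, per-line `doubling_h`, `day0_count`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- sim_panel(config)
  with_seed(child_seed(config$seed, 101), {
    doubling <- stats::runif(config$n_cell_lines, config$doubling_range[1],
                             config$doubling_range[2])
    names(doubling) <- panel$lines
    pars <- config$gr_params
    if (is.null(pars)) pars <- draw_gr_params(config, panel$drugs, panel$lines)
    need <- c("drug", "cell_line", "GR_inf", "GEC50", "hill")
    if (!all(need %in% names(pars))) {
      stop("gr_params must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    pkey <- paste(pars$drug, pars$cell_line, sep = "\r")
    noise <- function(n) exp(stats::rnorm(n, 0, config$count_noise_sd))

    rows <- list()
    for (ln in panel$lines) {
      # day-0 untreated plate, grown in parallel until treatment
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = ln, drug = VEHICLE, concentration = 0, time_h = 0,
        plate_id = paste(ln, "day0", sep = "_"),
        well = sprintf("%s_day0_w%02d", ln, seq_len(config$n_day0_wells)),
        replicate = seq_len(config$n_day0_wells),
        target_class = NA_character_,
        count = config$day0_count * noise(config$n_day0_wells),
        stringsAsFactors = FALSE)
      x_ctrl_true <- config$day0_count * 2^(config$duration_h / doubling[[ln]])
      for (j in seq_len(config$J)) {
        plate <- paste(ln, "72h", "P", j, sep = "_")
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = ln, drug = VEHICLE, concentration = 0,
          time_h = config$duration_h, plate_id = plate,
          well = sprintf("%s_c%02d", plate, seq_len(config$N)),
          replicate = seq_len(config$N), target_class = NA_character_,
          count = x_ctrl_true * noise(config$N), stringsAsFactors = FALSE)
        grid <- expand.grid(dose = config$doses, drug = panel$drugs,
                            stringsAsFactors = FALSE)
        pix <- match(paste(grid$drug, ln, sep = "\r"), pkey)
        if (anyNA(pix)) {
          stop("gr_params missing for some (drug, cell line) pairs", call. = FALSE)
        }
        gr_true <- gr_curve(grid$dose, pars$GR_inf[pix], pars$GEC50[pix],
                            pars$hill[pix])
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = ln, drug = grid$drug, concentration = grid$dose,
          time_h = config$duration_h, plate_id = plate,
          well = sprintf("%s_t%04d", plate, seq_len(nrow(grid))),
          replicate = j,
          target_class = unname(panel$drug_class[grid$drug]),
          count = count_from_gr(gr_true, x_ctrl_true, config$day0_count) *
            noise(nrow(grid)),
          stringsAsFactors = FALSE)
      }
    }
    list(counts = do.call(rbind, rows),
         truth = list(gr_params = pars, doubling_h = doubling,
                      day0_count = config$day0_count, config = config))
  })
}

#' Simulate a drug-combination checkerboard
#'
#' Generates viable-cell counts for a two-drug dose grid (both single
#' agents at the config's dose series plus a zero dose, and every dose
#' pair) across biological replicates. In `bliss_independent` mode the
#' combination satisfies
#' `(1 - GR_AB) = (1 - GR_A) + (1 - GR_B) - (1 - GR_A)(1 - GR_B)` exactly
#' before noise; `synergistic` adds `planted_eob` to the combined effect
#' at every interior dose pair (or a dose-bump-weighted amount with
#' `eob_shape = "bump"`); `antagonistic` subtracts it.
#'
#' @param config a [simulation_config()].
#' @param mode `"bliss_independent"`, `"synergistic"`, or `"antagonistic"`.
#' @param params_a,params_b single-agent curve parameters, lists with
#'   `GR_inf`, `GEC50`, `hill`.
#' @param planted_eob magnitude of the planted excess over Bliss
#'   (default 0.3).
#' @param eob_shape `"uniform"` (constant planted EOB on interior cells)
#'   or `"bump"` (peaked at intermediate dose pairs).
#' @param n_bio_reps biological replicates, each with its own day-0 and
#'   control wells (default 3).
#' @param cell_line label for the simulated line.
#' @return list with `counts` (long data.frame: `conc_a`, `conc_b`,
#'   `time_h`, `plate_id`, `replicate`, `count`; day-0 rows at
#'   `time_h = 0`) and `truth` (the planted EOB grid and GR grids).
#' @export
simulate_combo <- function(config, mode = c("bliss_independent", "synergistic",
                                            "antagonistic"),
                           params_a = list(GR_inf = -0.2, GEC50 = 1, hill = 2),
                           params_b = list(GR_inf = 0.3, GEC50 = 0.5, hill = 1.5),
                           planted_eob = 0.3, eob_shape = c("uniform", "bump"),
                           n_bio_reps = 3, cell_line = "line01") {
  stopifnot(inherits(config, "simulation_config"))
  mode <- match.arg(mode)
  eob_shape <- match.arg(eob_shape)
  with_seed(child_seed(config$seed, 202), {
    doses <- c(0, config$doses)
    grid <- expand.grid(conc_a = doses, conc_b = doses)
    gr_a <- ifelse(grid$conc_a == 0, 1,
                   gr_curve(grid$conc_a, params_a$GR_inf, params_a$GEC50,
                            params_a$hill))
    gr_b <- ifelse(grid$conc_b == 0, 1,
                   gr_curve(grid$conc_b, params_b$GR_inf, params_b$GEC50,
                            params_b$hill))
    eff <- (1 - gr_a) + (1 - gr_b) - (1 - gr_a) * (1 - gr_b)
    interior <- grid$conc_a > 0 & grid$conc_b > 0
    planted <- rep(0, nrow(grid))
    if (mode != "bliss_independent") {
      shape <- if (eob_shape == "bump") {
        ua <- (match(grid$conc_a, doses) - 1) / (length(doses) - 1)
        ub <- (match(grid$conc_b, doses) - 1) / (length(doses) - 1)
        16 * ua * (1 - ua) * ub * (1 - ub) / 1  # peaks mid-grid
      } else rep(1, nrow(grid))
      sgn <- if (mode == "synergistic") 1 else -1
      planted <- sgn * planted_eob * shape * interior
    }
    gr_ab <- 1 - (eff + planted)

    doubling <- stats::runif(1, config$doubling_range[1], config$doubling_range[2])
    x_ctrl_true <- config$day0_count * 2^(config$duration_h / doubling)
    noise <- function(n) exp(stats::rnorm(n, 0, config$count_noise_sd))
    rows <- list()
    for (r in seq_len(n_bio_reps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cell_line, conc_a = 0, conc_b = 0, time_h = 0,
        plate_id = sprintf("combo_r%d_day0", r), replicate = r,
        well = sprintf("r%d_day0_w%02d", r, seq_len(config$n_day0_wells)),
        count = config$day0_count * noise(config$n_day0_wells),
        stringsAsFactors = FALSE)
      plate <- sprintf("combo_r%d", r)
      # control wells (both doses zero) beyond the grid's own (0,0) cell
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cell_line, conc_a = 0, conc_b = 0,
        time_h = config$duration_h, plate_id = plate, replicate = r,
        well = sprintf("%s_c%02d", plate, seq_len(config$N)),
        count = x_ctrl_true * noise(config$N), stringsAsFactors = FALSE)
      keep <- !(grid$conc_a == 0 & grid$conc_b == 0)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cell_line, conc_a = grid$conc_a[keep],
        conc_b = grid$conc_b[keep], time_h = config$duration_h,
        plate_id = plate, replicate = r,
        well = sprintf("%s_t%03d", plate, seq_len(sum(keep))),
        count = count_from_gr(gr_ab[keep], x_ctrl_true, config$day0_count) *
          noise(sum(keep)),
        stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, rows),
         truth = list(grid = cbind(grid, GR_A = gr_a, GR_B = gr_b,
                                   GR_AB = gr_ab, planted_eob = planted),
                      mode = mode, params_a = params_a, params_b = params_b,
                      doubling_h = doubling, config = config))
  })
}
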