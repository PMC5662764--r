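#' Construct well metadata
#'
#' Builds the validated per-well annotation table shared by the expression
#' and count assays. One row per well.
#'
#' @param plate_id plate identifier.
#' @param well well identifier, unique within a plate.
#' @param cell_line cell line name.
#' @param drug drug name, or [VEHICLE] for vehicle-control wells.
#' @param concentration dose in micromolar; must be 0 exactly for vehicle
#'   wells and positive otherwise.
#' @param time_h time point in hours (3/24 for expression, 0/72 for counts).
#' @param replicate positive integer replicate index.
#' @param target_class optional drug target-class annotation.
#' @return a `data.frame` with one row per well.
#' @export
well_metadata <- function(plate_id, well, cell_line, drug, concentration,
                          time_h, replicate, target_class = NA_character_) {
  df <- data.frame(
    plate_id = as.character(plate_id),
    well = as.character(well),
    cell_line = as.character(cell_line),
    drug = as.character(drug),
    concentration = as.numeric(concentration),
    time_h = as.numeric(time_h),
    replicate = as.integer(replicate),
    target_class = as.character(target_class),
    stringsAsFactors = FALSE
  )
  validate_wells(df)
  df
}

is_vehicle_well <- function(wells) {
  imp <- toupper(wells$drug) == toupper(VEHICLE)
  if (!is.null(wells$is_control)) {
    expl <- wells$is_control
    if (!is.logical(expl)) expl <- toupper(as.character(expl)) %in% c("TRUE", "1", "T")
    return(expl)
  }
  imp
}

validate_wells <- function(wells) {
  req <- c("plate_id", "well", "cell_line", "drug", "concentration",
           "time_h", "replicate")
  miss <- setdiff(req, names(wells))
  if (length(miss) > 0) {
    stop("well metadata is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- paste(wells$plate_id, wells$well, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (plate_id, well) pairs: ",
         paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
               collapse = "; "), call. = FALSE)
  }
  veh <- is_vehicle_well(wells)
  bad <- xor(veh, wells$concentration == 0)
  if (any(bad)) {
    stop("concentration must be 0 exactly for vehicle wells and positive ",
         "otherwise; offending wells: ",
         paste(head(wells$well[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(wells)
}

gct_error <- function(line, msg) {
  stop(sprintf("malformed GCT (line %d): %s", line, msg), call. = FALSE)
}

# columns of well metadata coerced to numeric/integer on read
.numeric_meta <- c("concentration", "time_h")
.integer_meta <- c("replicate")

#' Read a GCT 1.3 expression file
#'
#' Parses the tab-delimited GCT 1.3 text container used for level-3 L1000
#' landmark data (978 genes x wells, quantile normalized) into a
#' [SummarizedExperiment::SummarizedExperiment]. Column metadata becomes
#' `colData` (well annotations), row metadata becomes `rowData`. The
#' older GCT 1.2 dialect (no column-metadata block) is rejected.
#'
#' @param path path to a GCT 1.3 text file.
#' @param require_well_meta if `TRUE` (default) the file must carry the
#'   well-annotation columns needed downstream (`plate_id`, `cell_line`,
#'   `drug`, `concentration`, `time_h`, `replicate`).
#' @return a `SummarizedExperiment` with assay `"exprs"`.
#' @seealso [write_gct()], [assemble_batches()]
#' @export
read_gct <- function(path, require_well_meta = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) gct_error(1, "fewer than 3 lines")
  ver <- trimws(lines[1])
  if (ver == "#1.2") {
    gct_error(1, "GCT 1.2 is not supported; expected the 1.3 dialect with a column-metadata block")
  }
  if (ver != "#1.3") gct_error(1, sprintf("expected '#1.3' header, found '%s'", ver))
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(dims) != 4) gct_error(2, "dimension line must have 4 tab-separated integers")
  dims <- suppressWarnings(as.integer(dims))
  if (anyNA(dims) || any(dims < 0)) gct_error(2, "non-integer dimension counts")
  nr <- dims[1]; nc <- dims[2]; nrm <- dims[3]; ncm <- dims[4]
  if (nc < 1) gct_error(2, "GCT requires at least one data column")
  want_len <- 1L + nrm + nc
  if (length(lines) != 2L + 1L + ncm + nr) {
    gct_error(length(lines),
              sprintf("declared %d data rows and %d column-metadata rows but file has %d lines",
                      nr, ncm, length(lines)))
  }
  split1 <- function(i) strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  hdr <- split1(3)
  if (length(hdr) != want_len) {
    gct_error(3, sprintf("header row has %d fields, expected %d", length(hdr), want_len))
  }
  row_meta_names <- if (nrm > 0) hdr[2:(1 + nrm)] else character(0)
  col_ids <- hdr[(2 + nrm):want_len]

  col_meta <- list()
  for (k in seq_len(ncm)) {
    ln <- 3L + k
    f <- split1(ln)
    if (length(f) != want_len) {
      gct_error(ln, sprintf("column-metadata row has %d fields, expected %d", length(f), want_len))
    }
    col_meta[[f[1]]] <- f[(2 + nrm):want_len]
  }

  gene_ids <- character(nr)
  row_meta <- matrix(NA_character_, nrow = nr, ncol = nrm)
  values <- matrix(NA_real_, nrow = nr, ncol = nc)
  for (i in seq_len(nr)) {
    ln <- 3L + ncm + i
    f <- split1(ln)
    if (length(f) != want_len) {
      gct_error(ln, sprintf("data row has %d fields, expected %d", length(f), want_len))
    }
    gene_ids[i] <- f[1]
    if (nrm > 0) row_meta[i, ] <- f[2:(1 + nrm)]
    v <- suppressWarnings(as.numeric(f[(2 + nrm):want_len]))
    if (anyNA(v)) gct_error(ln, "non-numeric or missing expression value")
    values[i, ] <- v
  }
  dimnames(values) <- list(gene_ids, col_ids)

  cd <- data.frame(well = col_ids, stringsAsFactors = FALSE)
  for (nm in names(col_meta)) {
    x <- col_meta[[nm]]
    if (nm %in% .numeric_meta) {
      x <- suppressWarnings(as.numeric(x))
      if (anyNA(x)) gct_error(3, sprintf("column metadata '%s' must be numeric", nm))
    } else if (nm %in% .integer_meta) {
      x <- suppressWarnings(as.integer(x))
    } else if (nm == "is_control") {
      x <- toupper(x) %in% c("TRUE", "1", "T")
    }
    cd[[nm]] <- x
  }
  if (require_well_meta) {
    req <- c("plate_id", "cell_line", "drug", "concentration", "time_h", "replicate")
    miss <- setdiff(req, names(cd))
    if (length(miss) > 0) {
      gct_error(3, paste0("missing well-metadata column(s): ", paste(miss, collapse = ", ")))
    }
  }
  rd <- if (nrm > 0) {
    as.data.frame(stats::setNames(as.data.frame(row_meta, stringsAsFactors = FALSE),
                                  row_meta_names))
  } else data.frame(row.names = gene_ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(cd, row.names = col_ids),
    rowData = S4Vectors::DataFrame(rd, row.names = gene_ids)
  )
}

#' Write a GCT 1.3 expression file
#'
#' Inverse of [read_gct()]: serializes a `SummarizedExperiment` (first
#' assay) with its `colData`/`rowData` as GCT 1.3 tab-delimited text.
#' Values are written at full double precision, so a read/write round trip
#' preserves them to better than 1e-6.
#'
#' @param se a `SummarizedExperiment` with at least one well (column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(se, path) {
  values <- SummarizedExperiment::assay(se, 1)
  if (ncol(values) < 1) stop("GCT requires at least one column (well)", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("expression matrix contains non-finite values; refusing to write", call. = FALSE)
  }
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  cd$well <- NULL  # the column id line carries the well name
  nr <- nrow(values); nc <- ncol(values)
  nrm <- ncol(rd); ncm <- ncol(cd)
  fmt <- function(x) {
    if (is.double(x)) vapply(x, function(v) format(v, digits = 15, scientific = FALSE),
                             character(1))
    else as.character(x)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("#1.3", paste(nr, nc, nrm, ncm, sep = "\t")), con)
  writeLines(paste(c("id", names(rd), colnames(values)), collapse = "\t"), con)
  for (nm in names(cd)) {
    writeLines(paste(c(nm, rep("na", nrm), fmt(cd[[nm]])), collapse = "\t"), con)
  }
  body <- vapply(seq_len(nr), function(i) {
    paste(c(rownames(values)[i],
            if (nrm > 0) as.character(unlist(rd[i, , drop = TRUE])) else character(0),
            fmt(values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Group expression wells into plate batches
#'
#' A batch is the set of experimental conditions for one cell line at one
#' time point, measured on `J` replicate plates that each carry their own
#' vehicle-control wells. Replicate `j` of a condition lives on plate `j`,
#' so the per-replicate differential signature is always computed against
#' same-plate controls (which also cancels additive plate effects).
#'
#' Conditions missing from some plates are retained with reduced `J` and
#' flagged `complete = FALSE`; conditions observed on fewer than 2 plates
#' are additionally flagged unusable for consistency scoring
#' (`scoreable = FALSE`) with a warning.
#'
#' @param se a `SummarizedExperiment` as returned by [read_gct()] or
#'   [simulate_expression()].
#' @return a list of `plate_batch` objects, one per (cell line, time point).
#' @export
assemble_batches <- function(se) {
  values <- SummarizedExperiment::assay(se, 1)
  wells <- as.data.frame(SummarizedExperiment::colData(se))
  if (is.null(wells$well)) wells$well <- colnames(values)
  validate_wells(wells)
  veh <- is_vehicle_well(wells)

  plates_all <- split(seq_len(nrow(wells)), wells$plate_id)
  n_ctrl <- vapply(plates_all, function(ix) sum(veh[ix]), integer(1))
  if (any(n_ctrl < 2)) {
    stop("every plate needs >= 2 vehicle-control wells; offending plate(s): ",
         paste(names(plates_all)[n_ctrl < 2], collapse = ", "), call. = FALSE)
  }

  treated_ix <- which(!veh)
  fac <- paste(wells$cell_line, wells$time_h, sep = "\r")
  batches <- lapply(split(treated_ix, fac[treated_ix]), function(ix) {
    cl <- wells$cell_line[ix[1]]
    th <- wells$time_h[ix[1]]
    plate_ids <- sort(unique(wells$plate_id[ix]))
    controls <- lapply(plate_ids, function(p) {
      cix <- which(wells$plate_id == p & veh)
      values[, cix, drop = FALSE]
    })
    names(controls) <- plate_ids

    ckey <- paste(wells$drug[ix], wells$concentration[ix], sep = "\r")
    cond_split <- split(ix, ckey)
    treated <- vector("list", length(cond_split))
    meta <- vector("list", length(cond_split))
    for (ci in seq_along(cond_split)) {
      cix <- cond_split[[ci]]
      p <- wells$plate_id[cix]
      if (anyDuplicated(p)) {
        stop(sprintf("condition '%s %g' on plate %s has more than one replicate well",
                     wells$drug[cix[1]], wells$concentration[cix[1]],
                     p[duplicated(p)][1]), call. = FALSE)
      }
      ord <- order(match(p, plate_ids))
      m <- values[, cix[ord], drop = FALSE]
      colnames(m) <- p[ord]
      treated[[ci]] <- m
      meta[[ci]] <- data.frame(
        cell_line = cl, drug = wells$drug[cix[1]],
        concentration = wells$concentration[cix[1]], time_h = th,
        target_class = if (is.null(wells$target_class)) NA_character_
                       else wells$target_class[cix[1]],
        J_used = length(cix),
        complete = length(cix) == length(plate_ids),
        scoreable = length(cix) >= 2,
        stringsAsFactors = FALSE
      )
    }
    conditions <- do.call(rbind, meta)
    conditions$condition_key <- condition_key(conditions)
    names(treated) <- conditions$condition_key
    if (any(!conditions$scoreable)) {
      warning(sprintf("batch %s/%gh: %d condition(s) with J < 2 excluded from consistency scoring",
                      cl, th, sum(!conditions$scoreable)), call. = FALSE)
    }
    structure(list(
      cell_line = cl, time_h = th,
      M = length(treated), J = length(plate_ids),
      N = min(vapply(controls, ncol, integer(1))),
      plates = plate_ids, gene_ids = rownames(values),
      treated = treated, controls = controls, conditions = conditions
    ), class = "plate_batch")
  })
  names(batches) <- vapply(batches, function(b) paste(b$cell_line, b$time_h, sep = "_"),
                           character(1))
  message(sprintf("assembled %d batch(es) from %d treated and %d vehicle wells",
                  length(batches), sum(!veh), sum(veh)))
  batches[order(names(batches))]
}

#' Canonical condition key
#'
#' `cell_line|drug|concentration|time_h`, the unique identifier of a
#' perturbation used throughout the pipeline.
#' @param df a data.frame with columns `cell_line`, `drug`,
#'   `concentration`, `time_h`.
#' @return character vector of keys.
#' @export
condition_key <- function(df) {
  paste(df$cell_line, df$drug, format(df$concentration, trim = TRUE, digits = 8),
        df$time_h, sep = "|")
}

#' @export
print.plate_batch <- function(x, ...) {
  cat(sprintf("plate_batch: %s at %g h — M = %d conditions, J = %d plates, N = %d controls/plate, G = %d genes\n",
              x$cell_line, x$time_h, x$M, x$J, x$N, length(x$gene_ids)))
  invisible(x)
}
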