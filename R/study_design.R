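#' Three-fold dilution series for one drug
#'
#' Builds the descending dose series used on one axis of a checkerboard
#' plate: `n_nonzero` serial dilutions of `max_conc` by `factor`, followed by
#' a single zero dose (the solvent-only control). Concentrations are stored
#' unrounded; rounding happens only at presentation via
#' [dose_series_values()].
#'
#' @param max_conc highest concentration in the series (uM), `> 0`.
#' @param factor dilution ratio between consecutive doses, `> 1` (default 3).
#' @param n_nonzero number of non-zero doses (default 5, giving 6 doses per
#'   axis including zero).
#' @param decimals decimal places used when the series is printed or exported
#'   (default 4).
#' @return An object of class `dose_series` with fields `max_conc`, `factor`,
#'   `n_nonzero`, `decimals` and `values` (unrounded, descending, final
#'   entry 0).
#' @examples
#' s <- dilution_series(5, 3, 5)
#' dose_series_values(s)          # 5.0000 1.6667 0.5556 0.1852 0.0617 0.0000
#' @export
dilution_series <- function(max_conc, factor = 3, n_nonzero = 5, decimals = 4) {
  if (!is.numeric(max_conc) || length(max_conc) != 1L || max_conc <= 0) {
    stopf("`max_conc` must be a single positive number, got %s", format(max_conc))
  }
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1) {
    stopf("`factor` must be a single number > 1, got %s", format(factor))
  }
  if (n_nonzero < 1) stopf("`n_nonzero` must be >= 1")
  values <- c(max_conc / factor^(seq_len(n_nonzero) - 1L), 0)
  structure(
    list(max_conc = max_conc, factor = factor, n_nonzero = as.integer(n_nonzero),
         decimals = as.integer(decimals), values = values),
    class = "dose_series"
  )
}

#' Presentation values of a dose series
#'
#' @param x a [dilution_series()] object.
#' @param decimals decimal places; defaults to the series' own setting.
#' @return Numeric vector, descending, rounded, final entry 0.
#' @export
dose_series_values <- function(x, decimals = x$decimals) {
  stopifnot(inherits(x, "dose_series"))
  round(x$values, decimals)
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf("<dose_series> %d-fold x%d from %g uM: %s\n",
              round(x$factor), x$n_nonzero, x$max_conc,
              paste(format(dose_series_values(x), trim = TRUE), collapse = " ")))
  invisible(x)
}

#' Registry of the screened drug pairs and their per-model dose maxima
#'
#' The 16 two-drug combinations of the glioblastoma screen, with the highest
#' concentration (uM) used for each drug in each of the three
#' patient-derived models (GBM8, GSC11, GSC7-10). All series descend from
#' these maxima in 3-fold dilutions.
#'
#' @return A data.frame in long form with columns `pair_id`, `drug1`,
#'   `drug2`, `cell_line`, `max1_uM`, `max2_uM` (16 pairs x 3 lines = 48
#'   rows).
#' @export
drug_pair_registry <- function() {
  pairs <- data.frame(
    pair_id = 1:16,
    drug1 = c("CGP-082996", "Lapatinib", "Lapatinib", "Lapatinib", "Erlotinib",
              "Erlotinib", "CGP-082996", "Lapatinib", "Lapatinib", "Lapatinib",
              "Tipifarnib", "Pazopanib", "PHA-665752", "Thapsigargin",
              "Bleomycin", "Lapatinib"),
    drug2 = c("Obatoclax mesylate", "Gemcitabine", "Vinorelbine",
              "Obatoclax mesylate", "Gemcitabine", "Vinorelbine",
              "Thapsigargin", "Thapsigargin", "Tipifarnib", "Bleomycin",
              "NVP-TAE684", "BMS-536924", "NVP-LAQ824", "Midostaurin",
              "A-770041", "CGP-082996"),
    stringsAsFactors = FALSE
  )
  # max1/max2 per cell line, in pair_id order
  gbm8   <- cbind(c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 1, 0.1, 0.1, 0.05, 1, 5),
                  c(0.5, 0.05, 0.05, 0.5, 0.05, 0.05, 0.05, 0.05, 1, 1, 0.5,
                    1, 0.05, 0.05, 1, 5))
  gsc11  <- cbind(c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 0.5, 0.05, 5, 5),
                  c(0.5, 5, 0.05, 0.5, 5, 0.05, 0.05, 0.05, 5, 5, 0.5, 5,
                    0.05, 1, 1, 5))
  gsc710 <- cbind(c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 0.1, 0.05, 1, 5),
                  c(0.5, 5, 0.05, 0.5, 5, 0.05, 0.05, 0.05, 5, 1, 0.5, 1,
                    0.05, 1, 5, 5))
  lines <- list(GBM8 = gbm8, GSC11 = gsc11, `GSC7-10` = gsc710)
  out <- do.call(rbind, lapply(names(lines), function(ln) {
    data.frame(pairs, cell_line = ln,
               max1_uM = lines[[ln]][, 1], max2_uM = lines[[ln]][, 2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Construct a study design
#'
#' Encodes the combinatorial layout of the screen: which cell lines and drug
#' pairs are tested, at which dose maxima, with how many technical
#' replicates, on which imaging days, and when drug exposure happens. Every
#' downstream module (simulation, decoding, synergy) uses this one
#' coordinate system: a plate is one (cell line, drug pair, replicate)
#' combination holding a `dose_grid_size` x `dose_grid_size` checkerboard in
#' which row/column index 0 carries zero dose, so well (0, 0) is the
#' untreated control.
#'
#' Imaging-day bookkeeping: the study's written schedule (days 1, 4, 8, 11,
#' 15, 18) is stored as `imaging_days`; the alternative figure convention
#' starting at day 0 is exposed as `imaging_days_alt`. The discrepancy is
#' carried, not resolved.
#'
#' @param registry long-form data.frame as returned by
#'   [drug_pair_registry()] (columns `pair_id`, `drug1`, `drug2`,
#'   `cell_line`, `max1_uM`, `max2_uM`). Subset it to build smaller designs.
#' @param n_replicates technical replicates (independent plates), default 2.
#' @param dose_grid_size doses per axis including zero, default 6.
#' @param imaging_days days on which images are taken.
#' @param exposure_windows list of `c(start, end)` day pairs during which
#'   drug is present.
#' @param dilution_factor fold-dilution between doses, default 3.
#' @param decimals presentation rounding for doses.
#' @return An object of class `study_design`.
#' @export
study_design <- function(registry = drug_pair_registry(),
                         n_replicates = 2,
                         dose_grid_size = 6,
                         imaging_days = c(1, 4, 8, 11, 15, 18),
                         exposure_windows = list(c(4, 8), c(11, 15)),
                         dilution_factor = 3,
                         decimals = 4) {
  need <- c("pair_id", "drug1", "drug2", "cell_line", "max1_uM", "max2_uM")
  if (!all(need %in% names(registry))) {
    stopf("`registry` must have columns: %s", paste(need, collapse = ", "))
  }
  if (n_replicates < 1) stopf("`n_replicates` must be >= 1")
  if (dose_grid_size < 1) stopf("`dose_grid_size` must be >= 1")
  imaging_days <- sort(unique(imaging_days))
  endpoint_day <- max(imaging_days)
  for (w in exposure_windows) {
    if (length(w) != 2L || w[1] >= w[2]) stopf("exposure windows must be c(start, end) with start < end")
    if (w[1] < 0 || w[2] > endpoint_day) stopf("exposure window [%g, %g] outside study days", w[1], w[2])
  }
  structure(
    list(
      registry = registry,
      cell_lines = unique(registry$cell_line),
      pair_table = unique(registry[, c("pair_id", "drug1", "drug2")]),
      n_replicates = as.integer(n_replicates),
      dose_grid_size = as.integer(dose_grid_size),
      imaging_days = imaging_days,
      imaging_days_alt = sort(unique(replace(imaging_days, imaging_days == min(imaging_days), 0))),
      exposure_windows = exposure_windows,
      endpoint_day = endpoint_day,
      dilution_factor = dilution_factor,
      decimals = as.integer(decimals)
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d cell line(s) x %d pair(s) x %d replicate(s), %dx%d grid\n",
    length(x$cell_lines), nrow(x$pair_table), x$n_replicates,
    x$dose_grid_size, x$dose_grid_size))
  cat(sprintf("  imaging days: %s (endpoint %g); exposure: %s\n",
              paste(x$imaging_days, collapse = ", "), x$endpoint_day,
              paste(vapply(x$exposure_windows,
                           function(w) sprintf("%g-%g", w[1], w[2]), ""),
                    collapse = ", ")))
  invisible(x)
}

# Ascending dose vector (zero first) for one drug axis of one plate.
ascending_doses <- function(max_conc, design) {
  if (design$dose_grid_size == 1L) return(0)
  s <- dilution_series(max_conc, design$dilution_factor,
                       n_nonzero = design$dose_grid_size - 1L,
                       decimals = design$decimals)
  rev(s$values)
}

#' Enumerate every culture well of a design
#'
#' Expands the factorial layout into one record per well. Row index `row`
#' follows drug 1 and column index `col` follows drug 2, both 0-based and
#' ascending in dose from index 0 = zero dose, so `(0, 0)` is the single
#' untreated well of each plate.
#'
#' @param design a [study_design()].
#' @return data.frame with columns `plate_id`, `cell_line`, `pair_id`,
#'   `drug1`, `drug2`, `replicate`, `row`, `col`, `dose1_uM`, `dose2_uM`,
#'   `well_index` (1-based within plate). At full study scale (3 lines, 16
#'   pairs, 2 replicates, 6x6 grid) this is 3456 wells per imaging day.
#' @export
enumerate_wells <- function(design) {
  stopifnot(inherits(design, "study_design"))
  g <- design$dose_grid_size
  reg <- design$registry
  plates <- merge(reg, data.frame(replicate = seq_len(design$n_replicates)))
  plates <- plates[order(plates$cell_line, plates$pair_id, plates$replicate), ]
  grid <- expand.grid(col = 0:(g - 1L), row = 0:(g - 1L))[, c("row", "col")]
  out <- do.call(rbind, lapply(seq_len(nrow(plates)), function(i) {
    p <- plates[i, ]
    d1 <- ascending_doses(p$max1_uM, design)
    d2 <- ascending_doses(p$max2_uM, design)
    data.frame(
      plate_id = sprintf("%s_p%02d_r%d", gsub("[^A-Za-z0-9]+", "", p$cell_line),
                         p$pair_id, p$replicate),
      cell_line = p$cell_line, pair_id = p$pair_id,
      drug1 = p$drug1, drug2 = p$drug2, replicate = p$replicate,
      row = grid$row, col = grid$col,
      dose1_uM = d1[grid$row + 1L], dose2_uM = d2[grid$col + 1L],
      well_index = seq_len(g * g),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a plate-map CSV
#'
#' Flat serialization of [enumerate_wells()] so a design can travel with a
#' dataset.
#'
#' @param design a [study_design()].
#' @param path CSV file path.
#' @return `write_plate_map()` returns the path invisibly;
#'   `read_plate_map()` returns the well data.frame.
#' @export
write_plate_map <- function(design, path) {
  wells <- enumerate_wells(design)
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
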