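#' Pharmacology parameters for a simulated drug pair
#'
#' The simulator's ground-truth pharmacology: each drug acts through a Hill
#' effect \eqn{e_i(d) = d^{h_i} / (d^{h_i} + ec50_i^{h_i})} in `[0, 1)`, the
#' two effects combine by independent action with a tunable excess term
#' ([drug_effect()]), and the combined effect drives a kill hazard scaled by
#' a shared `max_kill_rate`. A single kill-rate scale (rather than one per
#' drug) keeps independent action exactly multiplicative over time, which is
#' what makes the additivity oracle below exact; per-drug potency differences
#' are expressed through `ec50` and `slope`.
#'
#' These constants are synthetic stand-ins for unobserved true pharmacology;
#' defaults are chosen so a 3-fold series descending from 5 uM spans the
#' full effect range.
#'
#' @param ec50_1,ec50_2 half-effect concentrations (uM), `> 0`.
#' @param slope_1,slope_2 Hill slopes, `> 0`.
#' @param max_kill_rate saturating kill-rate scale (1/day), `>= 0`, shared by
#'   the pair.
#' @param synergy_alpha dimensionless excess interaction; 0 = exactly
#'   Bliss-additive truth, positive = synergistic, negative = antagonistic.
#' @return An object of class `drug_response_params`.
#' @export
drug_response_params <- function(ec50_1 = 0.5, slope_1 = 1.2,
                                 ec50_2 = 0.5, slope_2 = 1.2,
                                 max_kill_rate = 0.35,
                                 synergy_alpha = 0) {
  stopifnot(ec50_1 > 0, ec50_2 > 0, slope_1 > 0, slope_2 > 0,
            max_kill_rate >= 0)
  structure(list(ec50_1 = ec50_1, slope_1 = slope_1,
                 ec50_2 = ec50_2, slope_2 = slope_2,
                 max_kill_rate = max_kill_rate,
                 synergy_alpha = synergy_alpha),
            class = "drug_response_params")
}

#' Growth parameters for a simulated spheroid
#'
#' Logistic growth from a 750-cell seed (one spheroid per round-bottom
#' well). The default carrying capacity is set high enough that an untreated
#' spheroid stays well below saturation over an 18-day study, so growth is
#' near-exponential — the regime in which independent drug action composes
#' exactly multiplicatively. Set `capacity = Inf` for strictly exponential
#' growth.
#'
#' @param growth_rate per-capita growth rate (1/day).
#' @param initial_cells cells seeded per well (default 750).
#' @param capacity logistic carrying capacity (cells).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(growth_rate = 0.22, initial_cells = 750,
                          capacity = 1e6) {
  stopifnot(growth_rate > 0, initial_cells > 0, capacity > 0,
            initial_cells <= capacity)
  structure(list(growth_rate = growth_rate, initial_cells = initial_cells,
                 capacity = capacity),
            class = "growth_params")
}

# Single-drug Hill effect in [0, 1).
hill_effect <- function(d, ec50, slope) {
  ifelse(d <= 0, 0, 1 / (1 + (ec50 / d)^slope))
}

#' Combined kill effect of a two-drug dose
#'
#' Combines the two single-drug Hill effects by independent action with an
#' excess term:
#' \deqn{e = e_1 + e_2 - e_1 e_2 + \alpha\, e_1 e_2,}
#' clipped to `[0, 1]`. With `synergy_alpha = 0` this is the Bliss
#' independence composition of the two effects.
#'
#' @param d1,d2 doses (uM), `>= 0`. Vectorized.
#' @param params a [drug_response_params()].
#' @return Kill fraction(s) in `[0, 1]`.
#' @export
drug_effect <- function(d1, d2, params) {
  if (any(d1 < 0) || any(d2 < 0)) stopf("doses must be non-negative")
  e1 <- hill_effect(d1, params$ec50_1, params$slope_1)
  e2 <- hill_effect(d2, params$ec50_2, params$slope_2)
  e <- e1 + e2 - e1 * e2 + params$synergy_alpha * e1 * e2
  pmin(pmax(e, 0), 1)
}

# Kill hazard (1/day) for a combined effect e: k * (-log(1 - e)).
# First-order equal to k*e; chosen so that independent action composes
# multiplicatively in continuous time (hazards add exactly when alpha = 0).
kill_hazard <- function(e, max_kill_rate) {
  e <- pmin(e, 1 - 1e-12)
  max_kill_rate * (-log1p(-e))
}

# TRUE iff day t is inside any exposure window [start, end).
in_exposure <- function(t, windows) {
  for (w in windows) if (t >= w[1] && t < w[2]) return(TRUE)
  FALSE
}

# Integrate one well's cell count to each requested day.
# Multiplicative exponential-Euler update on a fixed-step grid augmented
# with the requested days and the window boundaries: exact for exponential
# growth (capacity = Inf), so rate additivity translates into exact
# viability products.
integrate_counts <- function(days, hazard, growth, windows, dt = 0.1) {
  t_max <- max(days)
  grid <- sort(unique(c(seq(0, t_max, by = dt), t_max, days,
                        pmin(unlist(windows), t_max))))
  grid <- grid[grid >= 0]
  n <- growth$initial_cells
  out <- numeric(length(days))
  out[days <= grid[1] + 1e-12] <- n
  for (s in seq_len(length(grid) - 1L)) {
    t0 <- grid[s]; step <- grid[s + 1L] - t0
    if (step <= 0) next
    g <- growth$growth_rate * (1 - n / growth$capacity)
    r <- if (in_exposure(t0, windows)) hazard else 0
    n <- n * exp((g - r) * step)
    hit <- abs(days - grid[s + 1L]) < 1e-9
    if (any(hit)) out[hit] <- n
  }
  out
}

#' Simulate ground-truth viability trajectories for a design
#'
#' Integrates a logistic growth / drug-kill model for every well of the
#' design and every requested day. During the exposure windows the
#' per-capita rate is reduced by the kill hazard derived from
#' [drug_effect()]; outside them the spheroid recovers at its natural
#' growth rate. Viability on a given day is the well's cell count relative
#' to the same plate's untreated well on that day (untreated = 100),
#' optionally perturbed by truncated Gaussian measurement noise; the
#' untreated reference itself is noise-free at exactly 100.
#'
#' @param design a [study_design()].
#' @param growth a [growth_params()].
#' @param response either a single [drug_response_params()] used for every
#'   pair, or a named list keyed by `"<cell_line>|<pair_id>"`.
#' @param noise_sd standard deviation of the viability noise (% viability,
#'   default 5); noise is truncated at 0.
#' @param seed integer seed; all randomness flows through it.
#' @param days days to record; defaults to the design's imaging days.
#' @param dt integration step (days).
#' @return data.frame: well coordinates plus `day`, `true_cell_count`,
#'   `true_viability_pct` (noise-free) and `viability_label` (noisy, the
#'   value an endpoint assay would report).
#' @export
simulate_trajectories <- function(design, growth = growth_params(),
                                  response = drug_response_params(),
                                  noise_sd = 5, seed = 1,
                                  days = design$imaging_days, dt = 0.1) {
  stopifnot(inherits(design, "study_design"))
  if (min(days) < 0) stopf("days must be non-negative")
  for (w in design$exposure_windows) {
    if (w[1] > max(design$imaging_days)) {
      stopf("exposure window [%g, %g] outside study days", w[1], w[2])
    }
  }
  wells <- enumerate_wells(design)
  days <- sort(unique(days))
  get_response <- function(line, pair) {
    if (inherits(response, "drug_response_params")) return(response)
    key <- paste0(line, "|", pair)
    response[[key]] %||% stopf("no response parameters for %s", key)
  }

  # untreated reference trajectory is shared by all plates (same growth)
  n_untreated <- integrate_counts(days, 0, growth, design$exposure_windows, dt)

  rows <- vector("list", nrow(wells))
  with_seed(seed, {
    for (i in seq_len(nrow(wells))) {
      w <- wells[i, ]
      p <- get_response(w$cell_line, w$pair_id)
      e <- drug_effect(w$dose1_uM, w$dose2_uM, p)
      hz <- kill_hazard(e, p$max_kill_rate)
      n_t <- if (hz == 0) n_untreated else {
        integrate_counts(days, hz, growth, design$exposure_windows, dt)
      }
      v_true <- 100 * n_t / n_untreated
      untreated <- w$row == 0L && w$col == 0L
      v_lab <- if (untreated) v_true else {
        pmax(v_true + stats::rnorm(length(days), 0, noise_sd), 0)
      }
      rows[[i]] <- data.frame(
        w, day = days, true_cell_count = n_t,
        true_viability_pct = v_true, viability_label = v_lab,
        row.names = NULL
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
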