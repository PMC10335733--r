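#' Synthetic activation time series
#'
#' Generates surface-activation assay data with the observation noise such
#' assays actually have: at each time the activated fraction is a binomial
#' proportion of `n_cells` counted cells, with success probability given by
#' the closed-form activation curve. Deterministic given the RNG seed.
#'
#' @param params A [kinetic_params()] object.
#' @param times Observation times (hours, strictly increasing).
#' @param n_cells Cells counted per time point.
#' @return A data frame with columns `time_h`, `fraction`, `n_cells`.
#'
#' @examples
#' set.seed(1)
#' kp <- kinetic_params(p0 = 0.10, tau_plus = 1.34, lambda_plus = 0.118)
#' make_activation_series(kp, seq(0.5, 3, 0.5), n_cells = 680)
#' @export
make_activation_series <- function(params, times, n_cells = 680) {
  stopifnot(inherits(params, "t6_kinetics"), all(diff(times) > 0),
            n_cells >= 1)
  p <- activation_probability(params, times)
  data.frame(time_h = times,
             fraction = rbinom(length(times), n_cells, p) / n_cells,
             n_cells = n_cells)
}

#' Synthetic sheath-count histogram
#'
#' Simulates `n_cells` independent reactors with the exact stochastic
#' simulation algorithm up to time `t` and tabulates their sheath counts,
#' mimicking a per-cell sheath-count microscopy census.
#'
#' @inheritParams make_activation_series
#' @param t Incubation time (hours).
#' @param n_cells Number of reactors (cells counted).
#' @param init_n Initial sheath rule for reactors starting activated (see
#'   [reactor_state()]).
#' @return A [sheath_histogram()].
#' @export
make_sheath_histogram <- function(params, t, n_cells = 1000,
                                  init_n = c("zero", "steady")) {
  stopifnot(n_cells >= 1)
  sim <- ssa_ensemble(n_cells, params, t, init_n = match.arg(init_n))
  tabulate_sheaths(sim$N)
}

#' Random non-overlapping toy population
#'
#' Places `n` cells uniformly at random without overlaps, for mechanics and
#' combat unit tests. A thin wrapper over the scenario seeding machinery
#' with neutral internal state (all cells inactive, no sheaths).
#'
#' @param n Number of cells.
#' @param arena An [arena()] object.
#' @param strain Strain index per cell (recycled).
#' @param radius Cap radius (micrometres).
#' @param init_length Total cell length at seeding (micrometres).
#' @return A cell table (see [new_cells()]).
#' @export
make_toy_population <- function(n, arena, strain = 1L, radius = 0.5,
                                init_length = 2) {
  cfg <- scenario_config(arena,
                         strains = list(strain_spec("toy", kinetic_params(),
                                                    r0 = 1)),
                         n_init = n, radius = radius,
                         init_length = init_length, t_end = 1)
  pos <- place_random_cells(cfg)
  cells <- new_cells(x = pos$x, y = pos$y, theta = pos$theta, ell = pos$ell,
                     radius = radius, strain = strain)
  cells$added <- pos$added
  cells$ell_birth <- cells$ell - pos$added
  cells
}
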