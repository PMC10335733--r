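#' Scenario configuration for an in-silico coincubation
#'
#' Collects everything needed to run a competition: the arena, the
#' competing strains, seeding, priming, time stepping and measurement
#' settings.
#'
#' Defaults follow the standard coincubation setup: seeding is
#' near-confluent (30% occupied area, emulating a spotted droplet of a
#' dense 1:1 mixture, so the two strains are in contact from the start),
#' the measurement window is a centred square (200 um on domains large
#' enough to hold it, half the domain otherwise), and the reaction step is
#' chosen so that the fastest internal rate satisfies the tau-leap bound
#' `rate * dt <= 0.1`.
#'
#' @param arena An [arena()] object.
#' @param strains A list of [strain_spec()] objects (two for a duel).
#' @param mix_ratio Initial number ratio across strains (default equal).
#' @param n_init Total number of seeded cells; by default enough cells to
#'   occupy `seed_occupancy` of the arena (or of the inoculum disc).
#' @param seed_occupancy Target occupied-area fraction at seeding, used
#'   only when `n_init` is `NULL`.
#' @param primed If `TRUE`, every seeded cell starts activated with a
#'   steady-state sheath load; if `FALSE` (unprimed), each cell starts
#'   activated with its strain's probability `p0` and the rest wait out
#'   `tau_plus` before stochastic switching.
#' @param t_end Simulated duration (hours).
#' @param dt Reaction time step (hours); default
#'   `min(0.005, 0.1 / max rate)`.
#' @param n_replicates Number of independent replicate runs.
#' @param seed Master seed; each replicate gets an independent stream drawn
#'   from it.
#' @param measure_window Axis-aligned rectangle `c(x0, x1, y0, y1)` for
#'   area-occupancy measurements; must lie inside the arena.
#' @param record_dt Cadence of time-series records (hours).
#' @param k_max Firing-slot count for the miss model (`Inf` disables
#'   misses whenever a contact exists).
#' @param delta_L Adder increment at which cells divide (micrometres).
#' @param div_angle_sd Angular noise at division (radians).
#' @param radius Cell cap radius (micrometres).
#' @param init_length Total length of seeded newborn cells (micrometres).
#' @param inoculum_radius If non-`NULL`, cells are seeded in a centred disc
#'   of this radius (range-expansion setup) instead of the whole arena.
#' @param max_cells Safety cap on the population size.
#' @return An object of class `t6_scenario`.
#' @export
scenario_config <- function(arena, strains, mix_ratio = NULL, n_init = NULL,
                            seed_occupancy = 0.3,
                            primed = FALSE, t_end = 24, dt = NULL,
                            n_replicates = 1, seed = 1,
                            measure_window = NULL, record_dt = 0.25,
                            k_max = 6, delta_L = 2, div_angle_sd = 0.05,
                            radius = 0.5, init_length = 2,
                            inoculum_radius = NULL, max_cells = 250000) {
  stopifnot(inherits(arena, "t6_arena"), length(strains) >= 1,
            all(vapply(strains, inherits, logical(1), "t6_strain")),
            t_end > 0, n_replicates >= 1, record_dt > 0,
            delta_L > 0, radius > 0, init_length > 2 * radius,
            seed_occupancy > 0, seed_occupancy < 0.5)
  if (is.null(mix_ratio)) mix_ratio <- rep(1, length(strains))
  stopifnot(length(mix_ratio) == length(strains), all(mix_ratio >= 0),
            sum(mix_ratio) > 0)
  if (is.null(n_init)) {
    seed_area <- if (is.null(inoculum_radius)) arena$Lx * arena$Ly
                 else pi * inoculum_radius^2
    mean_cell_area <- 2 * radius * (1.5 * init_length - 2 * radius) +
      pi * radius^2
    n_init <- max(2L, round(seed_occupancy * seed_area / mean_cell_area))
  }
  rates <- unlist(lapply(strains, function(s)
    c(s$kinetics$lambda_plus, s$kinetics$lambda_s, s$kinetics$lambda_f)))
  rates <- rates[is.finite(rates)]
  if (is.null(dt)) dt <- min(0.005, 0.1 / max(rates, 1e-9))
  if (max(rates) * dt > 0.1 + 1e-9)
    stop("dt violates the tau-leap bound rate * dt <= 0.1")
  if (is.null(measure_window)) {
    side_x <- if (arena$Lx >= 250) 200 else arena$Lx / 2
    side_y <- if (arena$Ly >= 250) 200 else arena$Ly / 2
    measure_window <- c((arena$Lx - side_x) / 2, (arena$Lx + side_x) / 2,
                        (arena$Ly - side_y) / 2, (arena$Ly + side_y) / 2)
  }
  stopifnot(length(measure_window) == 4,
            measure_window[1] >= 0, measure_window[2] <= arena$Lx,
            measure_window[3] >= 0, measure_window[4] <= arena$Ly,
            measure_window[1] < measure_window[2],
            measure_window[3] < measure_window[4])
  if (!is.null(inoculum_radius))
    stopifnot(inoculum_radius > 0,
              2 * inoculum_radius <= min(arena$Lx, arena$Ly))
  structure(list(arena = arena, strains = strains, mix_ratio = mix_ratio,
                 n_init = as.integer(n_init), seed_occupancy = seed_occupancy,
                 primed = primed, t_end = t_end,
                 dt = dt, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), measure_window = measure_window,
                 record_dt = record_dt, k_max = k_max, delta_L = delta_L,
                 div_angle_sd = div_angle_sd, radius = radius,
                 init_length = init_length,
                 inoculum_radius = inoculum_radius,
                 max_cells = as.integer(max_cells)),
            class = "t6_scenario")
}

#' Simulated wildtype and vasA-mutant strain presets
#'
#' Parameter sets for the two natural light-organ isolates used throughout:
#' ES401 (the faster activator: `p0 = 10%`, `lambda_plus = 0.6` per hour)
#' and FQ-A002 (the slower: `p0 = 5%`, `lambda_plus = 0.25` per hour), both
#' with `tau_plus = 1` h, `lambda_s = 21` per hour, `lambda_f = 6` per hour
#' (steady-state mean of 3.5 sheaths) and a 0.5 h lysis time. The
#' activation rates are the surface-assay estimates scaled five-fold, which
#' preserves their ratio. A `vasA` mutant cannot fire (`lambda_f = 0`) but
#' still expresses T6SS and pays the full growth penalty.
#'
#' @param vasA If `TRUE`, build the firing-deficient mutant.
#' @param r0 Base growth rate (per hour).
#' @param c Cost coefficient; the default gives both wildtype strains a
#'   penalised growth rate of 0.7 per hour.
#' @param tau_lys Lysis duration (hours).
#' @return A [strain_spec()].
#' @export
strain_es401 <- function(vasA = FALSE, r0 = 1, c = 0.3 / 21, tau_lys = 0.5) {
  strain_spec(if (vasA) "ES401_vasA" else "ES401",
              kinetic_params(p0 = 0.10, tau_plus = 1, lambda_plus = 0.6,
                             lambda_s = 21, lambda_f = if (vasA) 0 else 6),
              r0 = r0, c = c, tau_lys = tau_lys)
}

#' @rdname strain_es401
#' @export
strain_fqa002 <- function(vasA = FALSE, r0 = 1, c = 0.3 / 21, tau_lys = 0.5) {
  strain_spec(if (vasA) "FQA002_vasA" else "FQA002",
              kinetic_params(p0 = 0.05, tau_plus = 1, lambda_plus = 0.25,
                             lambda_s = 21, lambda_f = if (vasA) 0 else 6),
              r0 = r0, c = c, tau_lys = tau_lys)
}

place_random_cells <- function(config) {
  n <- config$n_init
  ar <- config$arena
  res <- place_cells_cpp(n, ar$Lx, ar$Ly, ar$boundary == "periodic",
                         config$radius, config$init_length,
                         !is.null(config$inoculum_radius),
                         ar$Lx / 2, ar$Ly / 2,
                         if (is.null(config$inoculum_radius)) 0
                         else config$inoculum_radius, 400L)
  if (res$placed < n)
    stop("could not place ", n, " non-overlapping cells; lower n_init or ",
         "enlarge the arena/inoculum")
  res[c("x", "y", "theta", "ell", "added")]
}

#' Seed the initial population of a coincubation
#'
#' Places `n_init` non-overlapping cells uniformly at random (in the whole
#' arena, or in the inoculum disc for range expansions) with random
#' orientations, assigns strains according to `mix_ratio`, and initialises
#' the internal T6SS state. Primed populations start fully activated with
#' sheath counts drawn from the steady state `Poisson(lambda_s /
#' lambda_f)`; unprimed populations start activated with probability `p0`
#' (activated cells again carry steady-state sheath loads, the rest none).
#'
#' @param config A [scenario_config()].
#' @return A cell table (see [new_cells()]).
#' @export
seed_coincubation <- function(config) {
  stopifnot(inherits(config, "t6_scenario"))
  pos <- place_random_cells(config)
  n <- config$n_init
  ns <- length(config$strains)
  prop <- config$mix_ratio / sum(config$mix_ratio)
  counts <- floor(prop * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(prop * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  strain <- sample(rep.int(seq_len(ns), counts))
  cells <- new_cells(x = pos$x, y = pos$y, theta = pos$theta, ell = pos$ell,
                     radius = config$radius, strain = strain)
  cells$added <- pos$added
  cells$ell_birth <- cells$ell - pos$added
  p0s <- vapply(config$strains, function(s) s$kinetics$p0, numeric(1))
  cells$G <- if (config$primed) TRUE else runif(n) < p0s[strain]
  nbar <- vapply(config$strains, function(s)
    if (s$kinetics$lambda_f > 0) s$kinetics$lambda_s / s$kinetics$lambda_f
    else 0, numeric(1))
  act <- which(cells$G & nbar[strain] > 0)
  cells$N[act] <- rpois(length(act), nbar[strain[act]])
  cells
}

strain_matrix <- function(strains) {
  m <- t(vapply(strains, function(s) c(
    s$kinetics$p0, s$kinetics$tau_plus, s$kinetics$lambda_plus,
    s$kinetics$lambda_s, s$kinetics$lambda_f,
    effective_growth_rate(s), s$tau_lys, s$r0), numeric(8)))
  colnames(m) <- c("p0", "tau_plus", "lambda_plus", "lambda_s", "lambda_f",
                   "r_eff", "tau_lys", "r0")
  m
}

run_one_replicate <- function(config, rep_seed) {
  set.seed(rep_seed)
  cells <- seed_coincubation(config)
  ar <- config$arena
  sm <- strain_matrix(config$strains)
  record_every <- max(1L, round(config$record_dt / config$dt))
  kmax <- if (is.finite(config$k_max)) as.integer(config$k_max) else 0L
  raw <- abm_run_cpp(
    cells$x, cells$y, cells$theta, cells$ell, cells$ell_birth, cells$added,
    cells$strain, cells$G, cells$N,
    ifelse(cells$status == "alive", 0L, 1L), cells$lysis_clock, cells$id,
    sm, config$radius, ar$Lx, ar$Ly, ar$boundary == "periodic",
    ar$carrying_capacity, ar$mech$k_elastic, ar$mech$zeta, ar$mech$zeta_rot,
    ar$mech$contact_eps, ar$mech$pressure_star, ar$mech$dt_mech,
    kmax, config$t_end, config$dt, record_every, config$delta_L,
    config$div_angle_sd, config$measure_window, config$max_cells)
  if (raw$status == "unstable")
    stop("mechanical instability during the run; reduce dt_mech")

  nm <- vapply(config$strains, function(s) s$name, character(1))
  series <- data.frame(time_h = raw$times)
  for (s in seq_along(nm)) series[[paste0("live_", nm[s])]] <- raw$live[, s]
  for (s in seq_along(nm)) series[[paste0("lysing_", nm[s])]] <- raw$lysing[, s]
  tot_area <- rowSums(raw$area)
  for (s in seq_along(nm))
    series[[paste0("areafrac_", nm[s])]] <-
      ifelse(tot_area > 0, raw$area[, s] / tot_area, NA_real_)
  series$occupancy <- raw$occupancy
  series <- series[!is.na(series$time_h), , drop = FALSE]

  fin <- raw$cells
  fin$status <- ifelse(fin$status == 0L, "alive", "lysing")
  fin$radius <- config$radius
  live_counts <- vapply(seq_along(nm), function(s)
    sum(fin$strain == s & fin$status == "alive"), numeric(1))
  names(live_counts) <- nm
  phi <- if (length(nm) == 2 && sum(live_counts) > 0)
    competition_outcome(live_counts[1], live_counts[2]) else NA_real_
  af <- tryCatch(area_occupancy(fin, config$measure_window),
                 error = function(e) setNames(rep(NA_real_, length(nm)), nm))
  names(af) <- nm
  structure(list(series = series, cells = fin, live_counts = live_counts,
                 phi = unname(phi), area_fraction = af,
                 kills = setNames(raw$kills, nm), births = raw$births,
                 removed = raw$removed, status = raw$status,
                 seed = rep_seed, strain_names = nm),
            class = "t6_result")
}

#' @export
print.t6_result <- function(x, ...) {
  cat("Competition replicate (status:", x$status, ")\n")
  cat("  final live counts:",
      paste(sprintf("%s = %d", names(x$live_counts), x$live_counts),
            collapse = ", "), "\n")
  if (!is.na(x$phi)) cat(sprintf("  phi = %.3f\n", x$phi))
  af <- x$area_fraction
  if (!all(is.na(af)))
    cat("  window area fractions:",
        paste(sprintf("%s = %.1f%%", names(af), 100 * af), collapse = ", "),
        "\n")
  invisible(x)
}

#' Run a competition scenario
#'
#' Executes the full agent-based model for each replicate of the scenario:
#' per reaction step the engine builds the contact graph, advances
#' activation and sheath synthesis/firing in every cell, resolves shots
#' against contacts (with misses, clonemate immunity and single-hit
#' lethality), updates lysis, grows and divides cells under pressure and
#' carrying-capacity attenuation, and relaxes the packing with overdamped
#' mechanics sub-steps. Runs are deterministic given the master seed.
#'
#' @param config A [scenario_config()].
#' @return An object of class `t6_competition`: list with `replicates` (one
#'   `t6_result` each), `phi` (final outcome statistic per replicate,
#'   resident = first strain), `area_fraction` (replicate x strain matrix
#'   of final window occupancy), `seeds`, and `config`.
#'
#' @examples
#' \donttest{
#' cfg <- scenario_config(arena(60), list(strain_es401(), strain_fqa002()),
#'                        t_end = 4, seed = 7)
#' res <- run_competition(cfg)
#' res$replicates[[1]]
#' }
#' @export
run_competition <- function(config) {
  stopifnot(inherits(config, "t6_scenario"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  reps <- lapply(seeds, function(s) run_one_replicate(config, s))
  phi <- vapply(reps, function(r) r$phi, numeric(1))
  af <- do.call(rbind, lapply(reps, function(r) r$area_fraction))
  structure(list(replicates = reps, phi = phi, area_fraction = af,
                 seeds = seeds, config = config),
            class = "t6_competition")
}

#' @export
print.t6_competition <- function(x, ...) {
  cat(sprintf("Competition: %d replicate(s), %g h, arena %g x %g um (%s)\n",
              length(x$replicates), x$config$t_end, x$config$arena$Lx,
              x$config$arena$Ly, x$config$arena$boundary))
  if (!all(is.na(x$phi)))
    cat(sprintf("  phi: mean %.3f (sd %.3f)\n", mean(x$phi, na.rm = TRUE),
                sd(x$phi)))
  if (!is.null(x$area_fraction) && !all(is.na(x$area_fraction)))
    cat("  mean window area fractions:",
        paste(sprintf("%s = %.1f%%", colnames(x$area_fraction),
                      100 * colMeans(x$area_fraction, na.rm = TRUE)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Per-strain occupied-area fractions in a measurement window
#'
#' The projected area of a live spherocylinder is `2 * radius * ell + pi *
#' radius^2`. Cells whose centre lies in the window contribute their full
#' area to their strain; fractions are relative to the total live cell area
#' in the window (so they sum to 1). Restricting measurement to a central
#' window avoids edge effects.
#'
#' @param cells A cell table.
#' @param window Rectangle `c(x0, x1, y0, y1)` in micrometres.
#' @return Named numeric vector of per-strain area fractions.
#' @export
area_occupancy <- function(cells, window) {
  stopifnot(length(window) == 4)
  live <- cells[cells$status == "alive", , drop = FALSE]
  inw <- live$x >= window[1] & live$x <= window[2] &
    live$y >= window[3] & live$y <= window[4]
  live <- live[inw, , drop = FALSE]
  if (nrow(live) == 0)
    stop("no live cell in the measurement window: occupancy undefined")
  areas <- 2 * live$radius * live$ell + pi * live$radius^2
  per <- tapply(areas, factor(live$strain, levels = sort(unique(cells$strain))),
                sum, default = 0)
  out <- per / sum(per)
  setNames(as.numeric(out), names(per))
}

#' Competition outcome statistic
#'
#' `phi = (n_res - n_comp) / (n_res + n_comp)`: +1 means resident
#' dominance, 0 coexistence, -1 competitor dominance.
#'
#' @param n_res,n_comp Final live counts of resident and competitor.
#' @return `phi` in `[-1, 1]`.
#' @export
competition_outcome <- function(n_res, n_comp) {
  stopifnot(n_res >= 0, n_comp >= 0)
  if (n_res + n_comp == 0)
    stop("phi is undefined when both populations are extinct")
  (n_res - n_comp) / (n_res + n_comp)
}

#' Competitor lethality parameter
#'
#' `beta = lambda_s_comp / (lambda_s_res + lambda_s_comp)`, the
#' competitor's share of total sheath production; `beta = 0.5` means
#' matched arsenals.
#'
#' @param lambda_s_comp,lambda_s_res Sheath production rates (per hour).
#' @return `beta` in `[0, 1]`.
#' @export
lethality_beta <- function(lambda_s_comp, lambda_s_res) {
  stopifnot(lambda_s_comp >= 0, lambda_s_res >= 0)
  if (lambda_s_comp + lambda_s_res == 0)
    stop("beta is undefined when both production rates are zero")
  lambda_s_comp / (lambda_s_res + lambda_s_comp)
}

#' Cost-lethality phase sweep
#'
#' Maps the competitive-outcome landscape of two fully primed lethal
#' strains that differ only in sheath production. The resident keeps its
#' production rate `lambda_s_res`; at each grid point the competitor
#' produces `lambda_s_res * beta / (1 - beta)` and both strains share the
#' cost coefficient `c = c_hat * r0 / lambda_s_res`. Each point is averaged
#' over `n_replicates` independent runs.
#'
#' @param base A [scenario_config()] whose first strain is the resident and
#'   second the competitor (their `lambda_s`, `c` and priming are
#'   overridden per point).
#' @param beta_grid Competitor lethality values in `[0, 0.5]`.
#' @param c_hat_grid Normalised cost values in `[0, 1]` (`c_hat = 1` stops
#'   the resident's growth entirely).
#' @param n_replicates Replicates per grid point (default from `base`).
#' @return A data frame with columns `beta`, `c_hat`, `phi_mean`, `phi_sd`,
#'   `n_rep`.
#' @export
phase_sweep <- function(base, beta_grid, c_hat_grid, n_replicates = NULL) {
  stopifnot(inherits(base, "t6_scenario"), length(base$strains) == 2,
            all(beta_grid >= 0), all(beta_grid <= 0.5),
            all(c_hat_grid >= 0), all(c_hat_grid <= 1))
  if (is.null(n_replicates)) n_replicates <- base$n_replicates
  res_strain <- base$strains[[1]]
  ls_res <- res_strain$kinetics$lambda_s
  r0 <- res_strain$r0
  stopifnot(ls_res > 0, r0 > 0)
  grid <- expand.grid(beta = beta_grid, c_hat = c_hat_grid)
  set.seed(base$seed)
  point_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    beta <- grid$beta[i]; c_hat <- grid$c_hat[i]
    ls_comp <- ls_res * beta / (1 - beta)
    cc <- c_hat * r0 / ls_res
    strains <- base$strains
    strains[[1]]$c <- cc
    strains[[2]]$c <- cc
    k2 <- strains[[2]]$kinetics
    strains[[2]]$kinetics <- kinetic_params(k2$p0, k2$tau_plus,
                                            k2$lambda_plus, ls_comp,
                                            k2$lambda_f)
    cfg <- base
    cfg$strains <- strains
    cfg$primed <- TRUE
    cfg$n_replicates <- as.integer(n_replicates)
    cfg$seed <- point_seeds[i]
    out <- run_competition(cfg)
    data.frame(beta = beta, c_hat = c_hat,
               phi_mean = mean(out$phi, na.rm = TRUE),
               phi_sd = sd(out$phi), n_rep = n_replicates)
  })
  do.call(rbind, rows)
}

#' Lethal-versus-target elimination experiment
#'
#' Unprimed coincubation of one lethal (firing) strain against one unarmed
#' target strain (`lambda_f = 0`). Tracks the target census over time,
#' averaged over replicates; used to compare how fast slow- and
#' fast-activating killers suppress a target.
#'
#' @param config A [scenario_config()] with exactly one strain whose
#'   `lambda_f > 0`.
#' @return A list of class `t6_target_result`: `competition` (the full
#'   [run_competition()] output), `target` (the target strain's name),
#'   `series` (data frame of `time_h`, per-replicate target live counts and
#'   their mean `target_mean`).
#' @export
run_target_elimination <- function(config) {
  stopifnot(inherits(config, "t6_scenario"), length(config$strains) == 2)
  lfs <- vapply(config$strains, function(s) s$kinetics$lambda_f, numeric(1))
  if (sum(lfs > 0) != 1)
    stop("exactly one strain must be able to fire (lambda_f > 0)")
  target_idx <- which(lfs == 0)
  out <- run_competition(config)
  nm <- config$strains[[target_idx]]$name
  col <- paste0("live_", nm)
  counts <- vapply(out$replicates, function(r) r$series[[col]],
                   numeric(nrow(out$replicates[[1]]$series)))
  counts <- matrix(counts, ncol = length(out$replicates))
  series <- data.frame(time_h = out$replicates[[1]]$series$time_h)
  colnames(counts) <- paste0("rep", seq_len(ncol(counts)))
  series <- cbind(series, counts)
  series$target_mean <- rowMeans(counts)
  structure(list(competition = out, target = nm, series = series),
            class = "t6_target_result")
}

#' Range-expansion coincubation
#'
#' Seeds the population in a circular inoculum inside an open (non-
#' periodic) arena and lets the colony expand freely. Reports, besides the
#' usual competition result, a survivor census with each final live cell's
#' radial position relative to the inoculum centre -- unarmed target cells
#' that persist do so in microcolonies at the expanding edge.
#'
#' @param config A [scenario_config()] with an open-boundary arena and a
#'   non-`NULL` `inoculum_radius`.
#' @return A list of class `t6_expansion_result`: `competition`, `census`
#'   (data frame: replicate, strain, cell id, radius from centre), and
#'   `colony_radius` per replicate.
#' @export
run_range_expansion <- function(config) {
  stopifnot(inherits(config, "t6_scenario"))
  if (config$arena$boundary != "open")
    stop("range expansion requires an open-boundary arena")
  if (is.null(config$inoculum_radius))
    stop("config$inoculum_radius must be set for a range expansion")
  out <- run_competition(config)
  cx <- config$arena$Lx / 2; cy <- config$arena$Ly / 2
  census <- do.call(rbind, lapply(seq_along(out$replicates), function(i) {
    fin <- out$replicates[[i]]$cells
    live <- fin[fin$status == "alive", , drop = FALSE]
    if (nrow(live) == 0) return(NULL)
    data.frame(replicate = i,
               strain = out$replicates[[i]]$strain_names[live$strain],
               id = live$id,
               radius_um = sqrt((live$x - cx)^2 + (live$y - cy)^2))
  }))
  colony_radius <- vapply(seq_along(out$replicates), function(i) {
    sub <- census[census$replicate == i, , drop = FALSE]
    if (nrow(sub) == 0) 0 else max(sub$radius_um) + config$radius
  }, numeric(1))
  if (any(colony_radius > min(config$arena$Lx, config$arena$Ly) / 2))
    warning("colony reached the arena bounds before t_end")
  structure(list(competition = out, census = census,
                 colony_radius = colony_radius),
            class = "t6_expansion_result")
}
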