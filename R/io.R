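#' Read and write activation series as CSV
#'
#' Headered CSV with columns `time_h`, `fraction` and optionally
#' `n_cells`. Values are written at full double precision so a round trip
#' is lossless.
#'
#' @param path File path.
#' @param series A data frame as produced by [make_activation_series()].
#' @return `read_activation_series` returns the data frame;
#'   `write_activation_series` returns `path` invisibly.
#' @export
read_activation_series <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_h", "fraction") %in% names(df)))
    stop("activation series CSV needs columns time_h and fraction")
  if (any(df$fraction < 0 | df$fraction > 1))
    stop("fractions must lie in [0, 1]")
  if (any(diff(df$time_h) <= 0))
    stop("times must be strictly increasing")
  df
}

#' @rdname read_activation_series
#' @export
write_activation_series <- function(series, path) {
  stopifnot(all(c("time_h", "fraction") %in% names(series)))
  write.csv(format(series, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write sheath histograms as CSV
#'
#' Headered CSV with columns `sheaths` (0..K) and `count`.
#'
#' @param path File path.
#' @param hist A [sheath_histogram()].
#' @return `read_sheath_histogram` returns a [sheath_histogram()];
#'   `write_sheath_histogram` returns `path` invisibly.
#' @export
read_sheath_histogram <- function(path) {
  df <- read.csv(path)
  if (!all(c("sheaths", "count") %in% names(df)))
    stop("sheath histogram CSV needs columns sheaths and count")
  df <- df[order(df$sheaths), ]
  if (!identical(as.integer(df$sheaths), seq_len(nrow(df)) - 1L))
    stop("sheath numbers must be contiguous from 0")
  sheath_histogram(df$count)
}

#' @rdname read_sheath_histogram
#' @export
write_sheath_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "t6_sheath_histogram"))
  write.csv(data.frame(sheaths = seq_along(hist$counts) - 1L,
                       count = hist$counts),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

scenario_defaults <- function() {
  list(Lx = 388, Ly = NULL, boundary = "periodic", carrying_capacity = 0.8,
       k_elastic = 20, zeta = 1, zeta_rot = NULL, contact_eps = 0.25,
       pressure_star = 1, dt_mech = 0.005,
       mix_ratio = NULL, n_init = NULL, seed_occupancy = 0.3,
       primed = FALSE, t_end = 24,
       dt = NULL, n_replicates = 1, seed = 1, measure_window = NULL,
       record_dt = 0.25, k_max = 6, delta_L = 2, div_angle_sd = 0.05,
       radius = 0.5, init_length = 2, inoculum_radius = NULL,
       max_cells = 250000)
}

strain_fields <- c("name", "p0", "tau_plus", "lambda_plus", "lambda_s",
                   "lambda_f", "r0", "c", "tau_lys")

#' Load a scenario configuration from a YAML file
#'
#' The file holds one mapping with any of the scalar scenario keys
#' (`Lx`, `Ly`, `boundary`, `carrying_capacity`, `k_elastic`, `zeta`,
#' `zeta_rot`, `contact_eps`, `pressure_star`, `dt_mech`, `mix_ratio`,
#' `n_init`, `seed_occupancy`, `primed`, `t_end`, `dt`, `n_replicates`, `seed`,
#' `measure_window`, `record_dt`, `k_max`, `delta_L`, `div_angle_sd`,
#' `radius`, `init_length`, `inoculum_radius`, `max_cells`) plus a
#' `strains` list whose entries have `name`, `p0`, `tau_plus`,
#' `lambda_plus`, `lambda_s`, `lambda_f`, `r0`, `c`, `tau_lys`. Unknown
#' keys are rejected with their path; omitted keys take the documented
#' defaults, and validation errors name the offending field.
#'
#' @param path Path to the YAML configuration.
#' @return A validated [scenario_config()].
#' @seealso [write_config()] for the resolved round-trip form.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  defaults <- scenario_defaults()
  known <- c(names(defaults), "strains")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$strains) || !length(raw$strains))
    stop("config needs a non-empty 'strains' list")
  strains <- lapply(seq_along(raw$strains), function(i) {
    s <- raw$strains[[i]]
    bad <- setdiff(names(s), strain_fields)
    if (length(bad))
      stop("unknown strain key(s) in strains[", i, "]: ",
           paste(bad, collapse = ", "))
    need <- setdiff(c("name", "p0", "lambda_s"), names(s))
    if (length(need))
      stop("strains[", i, "] is missing: ", paste(need, collapse = ", "))
    get_num <- function(key, default) {
      v <- if (is.null(s[[key]])) default else s[[key]]
      if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
        stop("strains[", i, "]$", key, " must be a non-negative number")
      v
    }
    strain_spec(as.character(s$name),
                kinetic_params(p0 = get_num("p0", 0),
                               tau_plus = get_num("tau_plus", 0),
                               lambda_plus = get_num("lambda_plus", 0),
                               lambda_s = get_num("lambda_s", 0),
                               lambda_f = get_num("lambda_f", 0)),
                r0 = get_num("r0", 1), c = get_num("c", 0),
                tau_lys = get_num("tau_lys", 0.5))
  })
  cfg <- modifyList(defaults, raw[setdiff(names(raw), "strains")],
                    keep.null = TRUE)
  if (is.null(cfg$Ly)) cfg$Ly <- cfg$Lx
  if (is.null(cfg$zeta_rot)) cfg$zeta_rot <- cfg$zeta / 12
  mech <- mechanics_params(k_elastic = cfg$k_elastic, zeta = cfg$zeta,
                           zeta_rot = cfg$zeta_rot,
                           contact_eps = cfg$contact_eps,
                           pressure_star = cfg$pressure_star,
                           dt_mech = cfg$dt_mech)
  ar <- arena(cfg$Lx, cfg$Ly, cfg$boundary,
              carrying_capacity = cfg$carrying_capacity, mech = mech)
  scenario_config(ar, strains,
                  mix_ratio = if (is.null(cfg$mix_ratio)) NULL
                              else as.numeric(cfg$mix_ratio),
                  n_init = cfg$n_init,
                  seed_occupancy = cfg$seed_occupancy,
                  primed = isTRUE(cfg$primed),
                  t_end = cfg$t_end, dt = cfg$dt,
                  n_replicates = cfg$n_replicates, seed = cfg$seed,
                  measure_window = if (is.null(cfg$measure_window)) NULL
                                   else as.numeric(cfg$measure_window),
                  record_dt = cfg$record_dt,
                  k_max = if (is.character(cfg$k_max)) Inf else cfg$k_max,
                  delta_L = cfg$delta_L, div_angle_sd = cfg$div_angle_sd,
                  radius = cfg$radius, init_length = cfg$init_length,
                  inoculum_radius = cfg$inoculum_radius,
                  max_cells = cfg$max_cells)
}

#' Write a resolved scenario configuration to YAML
#'
#' Writes every field of the (validated, defaults-resolved) scenario so
#' that [load_config()] on the written file reproduces it exactly.
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "t6_scenario"))
  ar <- config$arena
  out <- list(
    Lx = ar$Lx, Ly = ar$Ly, boundary = ar$boundary,
    carrying_capacity = ar$carrying_capacity,
    k_elastic = ar$mech$k_elastic, zeta = ar$mech$zeta,
    zeta_rot = ar$mech$zeta_rot, contact_eps = ar$mech$contact_eps,
    pressure_star = ar$mech$pressure_star, dt_mech = ar$mech$dt_mech,
    strains = lapply(config$strains, function(s) list(
      name = s$name, p0 = s$kinetics$p0, tau_plus = s$kinetics$tau_plus,
      lambda_plus = s$kinetics$lambda_plus, lambda_s = s$kinetics$lambda_s,
      lambda_f = s$kinetics$lambda_f, r0 = s$r0, c = s$c,
      tau_lys = s$tau_lys)),
    mix_ratio = config$mix_ratio, n_init = config$n_init,
    seed_occupancy = config$seed_occupancy, primed = config$primed, t_end = config$t_end, dt = config$dt,
    n_replicates = config$n_replicates, seed = config$seed,
    measure_window = config$measure_window, record_dt = config$record_dt,
    k_max = if (is.finite(config$k_max)) config$k_max else "inf",
    delta_L = config$delta_L, div_angle_sd = config$div_angle_sd,
    radius = config$radius, init_length = config$init_length,
    inoculum_radius = config$inoculum_radius,
    max_cells = config$max_cells)
  yaml::write_yaml(out, path, precision = 20)
  invisible(path)
}

#' Write competition results to an output directory
#'
#' Emits, per replicate, the time-series CSV (`series_rep<k>.csv`) and the
#' final cell snapshot (`snapshot_rep<k>.csv`), plus `metadata.json`
#' holding the fully resolved configuration, the master seed, the
#' per-replicate seed streams, package version, wall time and termination
#' status -- enough to reproduce the run bit-identically.
#'
#' @param result A `t6_competition` from [run_competition()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "t6_competition"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(result$replicates)) {
    r <- result$replicates[[i]]
    fs <- file.path(outdir, sprintf("series_rep%d.csv", i))
    write.csv(format(r$series, digits = 17, trim = TRUE), fs,
              row.names = FALSE, quote = FALSE)
    fc <- file.path(outdir, sprintf("snapshot_rep%d.csv", i))
    write.csv(format(r$cells, digits = 17, trim = TRUE), fc,
              row.names = FALSE, quote = FALSE)
    files <- c(files, fs, fc)
  }
  cfg_path <- file.path(outdir, "config.yml")
  write_config(result$config, cfg_path)
  meta <- list(
    package = "t6sim",
    version = as.character(packageVersion("t6sim")),
    master_seed = result$config$seed,
    replicate_seeds = result$seeds,
    n_replicates = length(result$replicates),
    status = vapply(result$replicates, function(r) r$status, character(1)),
    phi = result$phi,
    wall_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_file = basename(cfg_path))
  fm <- file.path(outdir, "metadata.json")
  jsonlite::write_json(meta, fm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, cfg_path, fm))
}

#' Draw a population snapshot
#'
#' Base-graphics rendering of the monolayer: each cell is drawn as a
#' capsule coloured by strain; lysing cells are faded.
#'
#' @param cells A cell table.
#' @param arena An [arena()] object (sets the plot limits).
#' @param col Colours per strain.
#' @param ... Passed to [plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_snapshot <- function(cells, arena, col = NULL, ...) {
  ns <- max(cells$strain)
  if (is.null(col)) col <- hcl.colors(max(2, ns), "Dark 2")
  plot(NA, xlim = c(0, arena$Lx), ylim = c(0, arena$Ly), asp = 1,
       xlab = "x (um)", ylab = "y (um)", ...)
  rect(0, 0, arena$Lx, arena$Ly, border = "grey60")
  tt <- seq(-pi / 2, pi / 2, length.out = 13)
  for (i in seq_len(nrow(cells))) {
    r <- cells$radius[i]; h <- cells$ell[i] / 2
    ca <- cos(cells$theta[i]); sa <- sin(cells$theta[i])
    # capsule outline in the body frame, then rotate and translate
    px <- c(h + r * cos(tt), -h + r * cos(tt + pi))
    py <- c(r * sin(tt), r * sin(tt + pi))
    cc <- col[cells$strain[i]]
    if (cells$status[i] != "alive") cc <- adjustcolor(cc, alpha.f = 0.3)
    polygon(cells$x[i] + px * ca - py * sa,
            cells$y[i] + px * sa + py * ca,
            col = cc, border = NA)
  }
  invisible(NULL)
}
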