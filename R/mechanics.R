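#' Mechanical interaction parameters
#'
#' Constants of the overdamped monolayer mechanics. Cells are
#' spherocylinders on a viscous substrate; overlapping surfaces repel with a
#' Hookean (linear-in-overlap) contact force, translation is damped in
#' proportion to cell length and rotation to length cubed, and local contact
#' pressure attenuates elongation.
#'
#' Defaults are chosen so that the mechanical relaxation time
#' `zeta / k_elastic` (0.05 h) is much shorter than a doubling time while
#' keeping the explicit sub-step `dt_mech` at the stability bound
#' `0.1 * zeta / k_elastic`.
#'
#' @param k_elastic Contact stiffness (force per micrometre of overlap).
#' @param zeta Translational drag per unit cell length.
#' @param zeta_rot Rotational drag scale (drag torque is
#'   `zeta_rot * length^3 * angular velocity`); default `zeta / 12`, the
#'   slender-rod ratio.
#' @param contact_eps Surface gap below which two cells count as "in
#'   contact" for T6SS firing (micrometres).
#' @param pressure_star Summed overlap (micrometres) at which growth is
#'   fully arrested.
#' @param dt_mech Mechanics sub-step (hours).
#' @return An object of class `t6_mech`.
#' @export
mechanics_params <- function(k_elastic = 20, zeta = 1, zeta_rot = zeta / 12,
                             contact_eps = 0.25, pressure_star = 1,
                             dt_mech = 0.005) {
  vals <- list(k_elastic = k_elastic, zeta = zeta, zeta_rot = zeta_rot,
               contact_eps = contact_eps, pressure_star = pressure_star,
               dt_mech = dt_mech)
  stopifnot(all(vapply(vals, function(v) is.numeric(v) && length(v) == 1 &&
                         is.finite(v) && v > 0, logical(1))))
  if (dt_mech > 0.1 * zeta / k_elastic + 1e-12)
    stop("dt_mech exceeds the stability bound 0.1 * zeta / k_elastic")
  structure(vals, class = "t6_mech")
}

#' Competition arena
#'
#' The 2D domain cells live in: a rectangle that is either periodic (a
#' confined colony interior, as used for duels) or open (for range
#' expansion from an inoculum). The carrying capacity bounds the fraction of
#' the domain area that cells can occupy; growth slows to zero as occupancy
#' approaches it.
#'
#' @param Lx,Ly Domain size in micrometres.
#' @param boundary `"periodic"` or `"open"`.
#' @param carrying_capacity Maximum occupied-area fraction, in `(0, 1]`.
#' @param mech A [mechanics_params()] object.
#' @return An object of class `t6_arena`.
#' @export
arena <- function(Lx, Ly = Lx, boundary = c("periodic", "open"),
                  carrying_capacity = 0.8, mech = mechanics_params()) {
  boundary <- match.arg(boundary)
  stopifnot(Lx > 0, Ly > 0, carrying_capacity > 0, carrying_capacity <= 1,
            inherits(mech, "t6_mech"))
  structure(list(Lx = Lx, Ly = Ly, boundary = boundary,
                 carrying_capacity = carrying_capacity, mech = mech),
            class = "t6_arena")
}

#' @export
print.t6_arena <- function(x, ...) {
  cat(sprintf("Arena %g x %g um (%s), carrying capacity %g\n",
              x$Lx, x$Ly, x$boundary, x$carrying_capacity))
  invisible(x)
}

#' Computational strain definition
#'
#' A strain couples T6SS kinetics to cell physiology: the base growth rate
#' `r0`, the cost coefficient `c` by which sheath production slows growth
#' (`r0' = r0 - c * lambda_s`, clamped at zero), and the lysis duration
#' `tau_lys` for which a killed cell of this strain keeps occupying space
#' before disintegrating.
#'
#' @param name Strain identifier.
#' @param kinetics A [kinetic_params()] object.
#' @param r0 Base growth rate without any T6SS expression (per hour).
#' @param c Cost coefficient (growth-rate units per unit `lambda_s`).
#' @param tau_lys Lysis duration after a lethal hit (hours).
#' @return An object of class `t6_strain`.
#'
#' @examples
#' es401 <- strain_spec("ES401",
#'   kinetic_params(0.10, 1, 0.6, 21, 6), r0 = 1, c = 0.3 / 21)
#' effective_growth_rate(es401)
#' @export
strain_spec <- function(name, kinetics, r0, c = 0, tau_lys = 0.5) {
  stopifnot(is.character(name), length(name) == 1,
            inherits(kinetics, "t6_kinetics"),
            is.numeric(r0), r0 >= 0, is.numeric(c), c >= 0,
            is.numeric(tau_lys), tau_lys >= 0)
  structure(list(name = name, kinetics = kinetics, r0 = r0, c = c,
                 tau_lys = tau_lys), class = "t6_strain")
}

#' @export
print.t6_strain <- function(x, ...) {
  cat(sprintf("Strain '%s': r0 = %g /h, cost c = %g, tau_lys = %g h, r0' = %g /h\n",
              x$name, x$r0, x$c, x$tau_lys, effective_growth_rate(x)))
  print(x$kinetics)
  invisible(x)
}

#' Cost-penalised growth rate of a strain
#'
#' Maintaining a T6SS arsenal diverts resources from growth: the effective
#' elongation rate of an activated cell is `max(0, r0 - c * lambda_s)`.
#'
#' @param strain A [strain_spec()] object.
#' @return The penalised growth rate (per hour, never negative).
#' @export
effective_growth_rate <- function(strain) {
  stopifnot(inherits(strain, "t6_strain"))
  max(0, strain$r0 - strain$c * strain$kinetics$lambda_s)
}

#' Create a population table of cells
#'
#' Cells are stored as a plain data frame with one row per cell and the
#' columns `id`, `strain` (index into the scenario's strain list), `x`, `y`
#' (centre, micrometres), `theta` (orientation, radians), `ell` (cylinder
#' length; total length is `ell + 2 * radius`), `radius`, `ell_birth`,
#' `added` (length added since birth, the adder bookkeeping), `G`
#' (activation flag), `N` (sheath count), `status` (`"alive"` or
#' `"lysing"`), and `lysis_clock` (hours until disintegration, lysing cells
#' only).
#'
#' @param x,y,theta,ell Cell geometry vectors (recycled to the longest).
#' @param radius Cap radius, a single value shared by all cells.
#' @param strain Strain index per cell.
#' @param G,N Internal T6SS state per cell.
#' @param id Cell identifiers (default `1..n`).
#' @return A `data.frame` of cells.
#' @export
new_cells <- function(x, y, theta = 0, ell = 1, radius = 0.5, strain = 1L,
                      G = FALSE, N = 0L, id = NULL) {
  n <- max(length(x), length(y), length(theta), length(ell), length(strain))
  stopifnot(length(radius) == 1, radius > 0)
  df <- data.frame(
    id = if (is.null(id)) seq_len(n) else id,
    strain = as.integer(rep_len(strain, n)),
    x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
    theta = rep_len(as.numeric(theta), n),
    ell = rep_len(as.numeric(ell), n), radius = radius,
    ell_birth = rep_len(as.numeric(ell), n), added = 0,
    G = rep_len(as.logical(G), n), N = as.integer(rep_len(N, n)),
    status = "alive", lysis_clock = 0)
  stopifnot(all(df$ell >= 0), all(df$N >= 0))
  df
}

#' Elongate cells by one time step
#'
#' Exponential elongation along the cylinder axis at the strain's effective
#' growth rate, scaled by a growth-attenuation factor: over a step `dt` the
#' total length is multiplied by `exp(r' * attenuation * dt)` (the exact
#' solution of length-proportional growth at constant attenuation). The cap
#' radius never changes, lysing cells never grow, and the added length is
#' accumulated for the adder division rule.
#'
#' @param cells A cell table (see [new_cells()]).
#' @param strains A list of [strain_spec()] objects indexed by
#'   `cells$strain`.
#' @param dt Time step (hours).
#' @param attenuation Scalar or per-cell factor in `[0, 1]` (see
#'   [growth_attenuation()]).
#' @return The updated cell table.
#' @export
grow_cell <- function(cells, strains, dt, attenuation = 1) {
  stopifnot(dt >= 0, all(attenuation >= 0), all(attenuation <= 1))
  att <- rep_len(attenuation, nrow(cells))
  rates <- vapply(strains, effective_growth_rate, numeric(1))[cells$strain]
  # inactive cells are not yet producing sheaths and grow at the base rate
  r0s <- vapply(strains, function(s) s$r0, numeric(1))[cells$strain]
  rates <- ifelse(cells$G, rates, r0s)
  alive <- cells$status == "alive"
  Ltot <- cells$ell + 2 * cells$radius
  dL <- ifelse(alive, Ltot * (exp(rates * att * dt) - 1), 0)
  cells$ell <- cells$ell + dL
  cells$added <- cells$added + dL
  cells
}

#' Growth attenuation from contact pressure and carrying capacity
#'
#' Local crowding and global saturation both slow elongation:
#' `max(0, 1 - overlap_sum / pressure_star) * max(0, 1 - occupied_fraction /
#' carrying_capacity)`.
#'
#' @param overlap_sum Per-cell sum of surface overlaps with neighbours
#'   (micrometres, >= 0).
#' @param occupied_fraction Fraction of the arena covered by cells.
#' @param arena A [arena()] object.
#' @return Attenuation factor(s) in `[0, 1]`.
#' @export
growth_attenuation <- function(overlap_sum, occupied_fraction, arena) {
  stopifnot(inherits(arena, "t6_arena"),
            all(overlap_sum >= 0), all(occupied_fraction >= 0))
  pmax(0, 1 - overlap_sum / arena$mech$pressure_star) *
    pmax(0, 1 - occupied_fraction / arena$carrying_capacity)
}

#' Divide cells that have completed their adder increment
#'
#' A cell divides once it has added `delta_L` of length since birth. The two
#' daughters lie end-to-end along the mother's axis, together covering the
#' mother's extent; each receives cylinder length
#' `(ell_mother - 2 * radius) / 2` (total length exactly half the
#' mother's), a reset adder, a small independent angular perturbation, the
#' mother's activation state and strain, and a Binomial(N, 1/2) share of the
#' mother's sheaths (the complement goes to the sister, so sheaths are
#' conserved exactly).
#'
#' @param cells A cell table.
#' @param delta_L Adder increment triggering division (micrometres).
#' @param angle_sd Standard deviation of the angular perturbation (radians).
#' @param arena Optional [arena()] for periodic wrapping of daughter
#'   centres.
#' @return The updated cell table (divided mothers replaced by daughters).
#' @export
maybe_divide <- function(cells, delta_L, angle_sd = 0.05, arena = NULL) {
  stopifnot(delta_L > 0)
  idx <- which(cells$status == "alive" & cells$added >= delta_L)
  if (!length(idx)) return(cells)
  next_id <- max(cells$id) + 1L
  mothers <- cells[idx, , drop = FALSE]
  Ltot <- mothers$ell + 2 * mothers$radius
  elld <- pmax(0, (mothers$ell - 2 * mothers$radius) / 2)
  ux <- cos(mothers$theta); uy <- sin(mothers$theta)
  off <- Ltot / 4
  n1 <- rbinom(nrow(mothers), mothers$N, 0.5)

  d1 <- mothers
  d1$x <- mothers$x - off * ux; d1$y <- mothers$y - off * uy
  d1$theta <- mothers$theta + rnorm(nrow(mothers), 0, angle_sd)
  d1$ell <- elld; d1$ell_birth <- elld; d1$added <- 0; d1$N <- n1

  d2 <- mothers
  d2$id <- seq.int(next_id, length.out = nrow(mothers))
  d2$x <- mothers$x + off * ux; d2$y <- mothers$y + off * uy
  d2$theta <- mothers$theta + rnorm(nrow(mothers), 0, angle_sd)
  d2$ell <- elld; d2$ell_birth <- elld; d2$added <- 0
  d2$N <- mothers$N - n1

  if (!is.null(arena) && arena$boundary == "periodic") {
    for (d in c("d1", "d2")) {
      dd <- get(d)
      dd$x <- dd$x %% arena$Lx; dd$y <- dd$y %% arena$Ly
      assign(d, dd)
    }
  }
  cells[idx, ] <- d1
  rbind(cells, d2)
}

#' Minimum distance between two segments
#'
#' Closest approach between 2D segments `a` and `b`, with the minimum-image
#' convention applied to `b` when the arena is periodic. This is the
#' geometric core of spherocylinder contact: two cells of radius `r` touch
#' when their axis segments come within `2 r`.
#'
#' @param a1,a2,b1,b2 Segment endpoints; numeric length-2 vectors or
#'   two-column matrices (vectorised row-wise).
#' @param arena Optional [arena()]; when periodic its minimum-image metric
#'   is used.
#' @return A list with `distance` and witness points `p` (on `a`) and `q`
#'   (on `b`, possibly shifted by a lattice vector).
#' @export
segment_min_distance <- function(a1, a2, b1, b2, arena = NULL) {
  as_mat <- function(v) if (is.matrix(v)) v else matrix(v, ncol = 2)
  a1 <- as_mat(a1); a2 <- as_mat(a2); b1 <- as_mat(b1); b2 <- as_mat(b2)
  periodic <- !is.null(arena) && arena$boundary == "periodic"
  res <- seg_min_dist_cpp(a1, a2, b1, b2,
                          if (periodic) arena$Lx else 0,
                          if (periodic) arena$Ly else 0, periodic)
  list(distance = res$distance, p = cbind(res$px, res$py),
       q = cbind(res$qx, res$qy))
}

#' Contact force and torque between two cells
#'
#' Hookean repulsion between overlapping spherocylinder surfaces: with
#' overlap `delta = max(0, 2 * radius - axis distance)` the force magnitude
#' is `k_elastic * delta`, directed along the line joining the closest axis
#' points, applied at the witness points (hence the torques). The pair
#' forces are exactly equal and opposite. Cells with coincident axes use a
#' deterministic fallback direction perpendicular to the first cell's axis.
#'
#' @param cell_a,cell_b Single-row cell tables.
#' @param arena An [arena()] object.
#' @return List with `force_a`, `force_b` (length-2 vectors), `torque_a`,
#'   `torque_b` (scalars), and `overlap` (micrometres).
#' @export
pair_interaction <- function(cell_a, cell_b, arena) {
  stopifnot(nrow(cell_a) == 1, nrow(cell_b) == 1, inherits(arena, "t6_arena"))
  r <- cell_a$radius
  ends <- function(cc) {
    h <- cc$ell / 2
    list(p1 = c(cc$x - h * cos(cc$theta), cc$y - h * sin(cc$theta)),
         p2 = c(cc$x + h * cos(cc$theta), cc$y + h * sin(cc$theta)))
  }
  ea <- ends(cell_a); eb <- ends(cell_b)
  sd <- segment_min_distance(ea$p1, ea$p2, eb$p1, eb$p2, arena)
  d <- sd$distance[1]
  delta <- max(0, 2 * r - d)
  if (delta == 0)
    return(list(force_a = c(0, 0), force_b = c(0, 0),
                torque_a = 0, torque_b = 0, overlap = 0))
  if (d > 1e-12) {
    nvec <- (sd$p[1, ] - sd$q[1, ]) / d
  } else {
    nvec <- c(-sin(cell_a$theta), cos(cell_a$theta))
  }
  f <- arena$mech$k_elastic * delta
  fa <- f * nvec
  # centre of b in a's frame (witness q is already minimum-imaged)
  dx <- cell_b$x - cell_a$x; dy <- cell_b$y - cell_a$y
  if (arena$boundary == "periodic") {
    dx <- dx - arena$Lx * floor(dx / arena$Lx + 0.5)
    dy <- dy - arena$Ly * floor(dy / arena$Ly + 0.5)
  }
  cb <- c(cell_a$x + dx, cell_a$y + dy)
  ta <- (sd$p[1, 1] - cell_a$x) * fa[2] - (sd$p[1, 2] - cell_a$y) * fa[1]
  tb <- (sd$q[1, 1] - cb[1]) * (-fa[2]) - (sd$q[1, 2] - cb[2]) * (-fa[1])
  list(force_a = fa, force_b = -fa, torque_a = ta, torque_b = tb,
       overlap = delta)
}

#' One overdamped mechanics sub-step
#'
#' Computes all pairwise contact forces and advances positions and
#' orientations by the overdamped update `dx = F / (zeta * L) * dt` and
#' `dtheta = T / (zeta_rot * L^3) * dt`, where `L` is the total cell
#' length. Lysing cells participate fully (corpses still occupy space).
#' Periodic coordinates are wrapped. A displacement larger than half the
#' cell radius in one sub-step signals numerical instability and raises an
#' error.
#'
#' @param cells A cell table.
#' @param arena An [arena()] object.
#' @param dt_mech Sub-step length (hours); defaults to the arena's
#'   mechanics parameter.
#' @return The updated cell table.
#' @export
step_mechanics <- function(cells, arena, dt_mech = NULL) {
  stopifnot(inherits(arena, "t6_arena"))
  if (is.null(dt_mech)) dt_mech <- arena$mech$dt_mech
  if (dt_mech > 0.1 * arena$mech$zeta / arena$mech$k_elastic + 1e-12)
    stop("dt_mech exceeds the stability bound 0.1 * zeta / k_elastic")
  if (nrow(cells) == 0) return(cells)
  r <- cells$radius[1]
  periodic <- arena$boundary == "periodic"
  fr <- contact_forces_cpp(cells$x, cells$y, cells$theta, cells$ell, r,
                           arena$Lx, arena$Ly, periodic,
                           arena$mech$k_elastic)
  Ltot <- cells$ell + 2 * r
  dx <- fr$fx / (arena$mech$zeta * Ltot) * dt_mech
  dy <- fr$fy / (arena$mech$zeta * Ltot) * dt_mech
  if (any(dx^2 + dy^2 > (r / 2)^2))
    stop("mechanical instability: displacement exceeded radius/2 in one sub-step")
  cells$x <- cells$x + dx
  cells$y <- cells$y + dy
  cells$theta <- cells$theta +
    fr$torque / (arena$mech$zeta_rot * Ltot^3) * dt_mech
  if (periodic) {
    cells$x <- cells$x %% arena$Lx
    cells$y <- cells$y %% arena$Ly
  }
  cells
}
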