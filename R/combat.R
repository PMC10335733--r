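#' Build the cell-cell contact graph
#'
#' Two cells are "in contact" -- and therefore possible T6SS targets for
#' one another -- when the gap between their spherocylinder surfaces (axis
#' distance minus `2 * radius`) is at most the arena's `contact_eps`.
#' Lysing cells are included: corpses still occupy space and can absorb
#' (shield) shots. The graph is symmetric and has no self-contacts.
#'
#' @param cells A cell table (see [new_cells()]).
#' @param arena An [arena()] object.
#' @return An object of class `t6_contacts`: list with `adjacency` (a list
#'   of neighbour row indices per cell) and `pairs` (matrix of contact
#'   pairs with distances).
#' @export
build_contacts <- function(cells, arena) {
  stopifnot(inherits(arena, "t6_arena"))
  n <- nrow(cells)
  adjacency <- rep(list(integer(0)), n)
  pairs <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("i", "j", "gap")))
  if (n >= 2) {
    r <- cells$radius[1]
    eps <- arena$mech$contact_eps
    hits <- cell_pairs_cpp(cells$x, cells$y, cells$theta, cells$ell, r,
                           arena$Lx, arena$Ly,
                           arena$boundary == "periodic", eps)
    if (nrow(hits)) {
      gap <- hits[, "distance"] - 2 * r
      keep <- gap <= eps
      hits <- hits[keep, , drop = FALSE]
      gap <- gap[keep]
      if (nrow(hits)) {
        pairs <- cbind(i = hits[, "i"], j = hits[, "j"], gap = gap)
        for (k in seq_len(nrow(hits))) {
          i <- as.integer(hits[k, "i"]); j <- as.integer(hits[k, "j"])
          adjacency[[i]] <- c(adjacency[[i]], j)
          adjacency[[j]] <- c(adjacency[[j]], i)
        }
      }
    }
  }
  structure(list(adjacency = adjacency, pairs = pairs, n = n),
            class = "t6_contacts")
}

#' Resolve the shots fired by one cell
#'
#' Each shot independently selects a target slot: with `k` cells in contact
#' there are `k` contact slots plus `max(0, k_max - k)` void slots, all
#' equally likely. A void slot is a miss into the intercellular milieu. A
#' contact slot hits that neighbour: a clonemate survives unharmed
#' (`hit_clonemate`), an already-lysing cell absorbs the shot (`hit_dead`),
#' and a live non-clonal cell is killed (`kill`) -- it ceases function
#' immediately, becoming `lysing` with its strain's `tau_lys` on the clock.
#'
#' @param cells A cell table.
#' @param shooter Row index of the firing cell (must be alive).
#' @param shots Number of sheaths fired this step (>= 0), e.g. from
#'   [step_sheath_dynamics()].
#' @param contacts A [build_contacts()] graph for `cells`.
#' @param strains List of [strain_spec()] objects (for the victim's lysis
#'   time).
#' @param k_max Total number of firing slots; `Inf` means a shot always
#'   finds a contact when at least one exists.
#' @return A list with the updated `cells` and an `outcomes` data frame
#'   (`shooter_id`, `result`, `target_id`).
#' @export
resolve_firing <- function(cells, shooter, shots, contacts, strains,
                           k_max = 6) {
  stopifnot(inherits(contacts, "t6_contacts"), shots >= 0,
            shooter >= 1, shooter <= nrow(cells))
  if (cells$status[shooter] != "alive") stop("shooter must be alive")
  out <- data.frame(shooter_id = integer(0), result = character(0),
                    target_id = integer(0))
  if (shots == 0)
    return(list(cells = cells, outcomes = out))
  nbrs <- contacts$adjacency[[shooter]]
  k <- length(nbrs)
  slots <- if (is.finite(k_max)) max(k, k_max) else max(k, 1)
  res <- character(shots)
  tgt <- rep(NA_integer_, shots)
  for (s in seq_len(shots)) {
    u <- floor(runif(1) * slots) + 1
    if (u > k) {
      res[s] <- "miss"
      next
    }
    j <- nbrs[u]
    tgt[s] <- cells$id[j]
    if (cells$strain[j] == cells$strain[shooter]) {
      res[s] <- "hit_clonemate"
    } else if (cells$status[j] != "alive") {
      res[s] <- "hit_dead"
    } else {
      res[s] <- "kill"
      cells$status[j] <- "lysing"
      cells$lysis_clock[j] <- strains[[cells$strain[j]]]$tau_lys
    }
  }
  out <- data.frame(shooter_id = cells$id[shooter], result = res,
                    target_id = tgt)
  list(cells = cells, outcomes = out)
}

#' Advance the lysis lifecycle
#'
#' Lysing cells count down their clock and disintegrate (are removed from
#' the population) once it reaches zero. Until removal they keep their
#' geometry and take part in mechanics and contact graphs. A lysis time of
#' zero removes the corpse at the end of the same step.
#'
#' @param cells A cell table.
#' @param dt Elapsed time this step (hours, > 0).
#' @return The cell table with clocks updated and disintegrated cells
#'   dropped.
#' @export
update_lysis <- function(cells, dt) {
  stopifnot(dt > 0)
  lysing <- cells$status == "lysing"
  cells$lysis_clock[lysing] <- cells$lysis_clock[lysing] - dt
  drop <- lysing & cells$lysis_clock <= 1e-12
  cells[!drop, , drop = FALSE]
}
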