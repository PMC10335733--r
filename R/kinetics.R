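#' Subcellular T6SS kinetic parameters
#'
#' Bundles the rate constants of the two-stage subcellular T6SS model for one
#' strain. Stage one is activation: a cell starts T6SS-ready ("activated",
#' `G+`) with probability `p0`; an inactive cell waits for `tau_plus` hours
#' and then switches on at constant rate `lambda_plus`. Stage two, which runs
#' only in activated cells, is sheath assembly and deployment: sheaths are
#' synthesised at rate `lambda_s` and each existing sheath fires
#' independently at rate `lambda_f` (an immigration--death process on the
#' sheath count `N`). There is no deactivation and no firing-independent
#' sheath decay.
#'
#' @param p0 Initial activated fraction, in `[0, 1]`.
#' @param tau_plus Activation waiting period before stochastic switching
#'   begins (hours, >= 0).
#' @param lambda_plus Activation rate once the waiting period has elapsed
#'   (per hour, >= 0; `Inf` is allowed and means instantaneous switching).
#' @param lambda_s Sheath synthesis rate in activated cells (per hour, >= 0).
#' @param lambda_f Per-sheath firing rate (per hour, >= 0).
#'
#' @return An object of class `t6_kinetics` (a named list of the five
#'   parameters).
#'
#' @examples
#' es401 <- kinetic_params(p0 = 0.10, tau_plus = 1.34, lambda_plus = 0.118,
#'                         lambda_s = 21, lambda_f = 6)
#' activation_probability(es401, c(0.5, 1, 2, 3))
#' steady_state_mean(es401)
#' @export
kinetic_params <- function(p0 = 0, tau_plus = 0, lambda_plus = 0,
                           lambda_s = 0, lambda_f = 0) {
  stopifnot(is.numeric(p0), length(p0) == 1, p0 >= 0, p0 <= 1)
  stopifnot(is.numeric(tau_plus), length(tau_plus) == 1, tau_plus >= 0,
            is.finite(tau_plus))
  stopifnot(is.numeric(lambda_plus), length(lambda_plus) == 1,
            lambda_plus >= 0)
  stopifnot(is.numeric(lambda_s), length(lambda_s) == 1, lambda_s >= 0,
            is.finite(lambda_s))
  stopifnot(is.numeric(lambda_f), length(lambda_f) == 1, lambda_f >= 0,
            is.finite(lambda_f))
  structure(list(p0 = p0, tau_plus = tau_plus, lambda_plus = lambda_plus,
                 lambda_s = lambda_s, lambda_f = lambda_f),
            class = "t6_kinetics")
}

#' @export
print.t6_kinetics <- function(x, ...) {
  cat("T6SS kinetic parameters:\n")
  cat(sprintf("  p0 = %g, tau+ = %g h, lambda+ = %g /h\n",
              x$p0, x$tau_plus, x$lambda_plus))
  cat(sprintf("  lambda_s = %g /h, lambda_f = %g /h", x$lambda_s, x$lambda_f))
  if (x$lambda_f > 0)
    cat(sprintf("  (steady-state mean N = %g)", x$lambda_s / x$lambda_f))
  cat("\n")
  invisible(x)
}

#' Closed-form activated fraction of a population
#'
#' The fraction of a large reactor population in the activated state at time
#' `t`: `p0` while `t < tau_plus`, and
#' `p0 + (1 - p0) * (1 - exp(-(t - tau_plus) * lambda_plus))` afterwards.
#' Non-decreasing in `t`, with limit 1 whenever `lambda_plus > 0`.
#'
#' @param params A [kinetic_params()] object.
#' @param t Time(s) in hours, >= 0. Vectorised.
#' @return Activated fraction(s) in `[p0, 1]`.
#' @export
activation_probability <- function(params, t) {
  stopifnot(inherits(params, "t6_kinetics"), is.numeric(t))
  if (any(t < 0)) stop("negative time is not allowed")
  dt <- t - params$tau_plus
  decay <- exp(-dt * params$lambda_plus)
  decay[dt == 0] <- 1  # guard 0 * Inf for instantaneous switching
  p <- params$p0 + (1 - params$p0) * (1 - decay)
  ifelse(dt < 0, params$p0, p)
}

#' Steady-state mean sheath number
#'
#' The immigration--death process of sheath assembly and firing relaxes to a
#' Poisson steady state with mean `lambda_s / lambda_f`.
#'
#' @param params A [kinetic_params()] object with `lambda_f > 0`.
#' @return The steady-state mean number of sheaths per activated cell.
#' @export
steady_state_mean <- function(params) {
  stopifnot(inherits(params, "t6_kinetics"))
  if (params$lambda_f <= 0)
    stop("lambda_f = 0: the sheath count has no finite steady state")
  params$lambda_s / params$lambda_f
}

#' Create an ensemble of cell-like reactors
#'
#' A reactor is a non-growing, non-dividing cell that carries only the T6SS
#' state: the activation flag `G` and the sheath count `N`. The ensemble is
#' stored as a list of parallel vectors plus a common clock `t`.
#'
#' @param n Number of reactors.
#' @param params A [kinetic_params()] object used to draw the initial state.
#' @param init_n Initial sheath count rule for reactors that start activated:
#'   `"zero"` (none) or `"steady"` (Poisson with the steady-state mean).
#' @return An object of class `t6_reactors`: `list(G, N, t)`.
#' @export
reactor_state <- function(n, params, init_n = c("zero", "steady")) {
  stopifnot(inherits(params, "t6_kinetics"), n >= 1)
  init_n <- match.arg(init_n)
  G <- runif(n) < params$p0
  N <- integer(n)
  if (init_n == "steady" && params$lambda_f > 0 && any(G))
    N[G] <- rpois(sum(G), params$lambda_s / params$lambda_f)
  structure(list(G = G, N = N, t = 0), class = "t6_reactors")
}

#' Advance the activation stage by one time step
#'
#' Tau-leap update of the activation process: an inactive reactor whose clock
#' has passed `tau_plus` switches on with probability
#' `1 - exp(-lambda_plus * dt)`; activated reactors never revert. The step
#' must satisfy `lambda_plus * dt <= 0.1` for the leap to be a good
#' approximation of the continuous-time process.
#'
#' @param state A `t6_reactors` ensemble (see [reactor_state()]).
#' @param params A [kinetic_params()] object.
#' @param dt Time step in hours, > 0.
#' @return The updated ensemble with its clock advanced by `dt`.
#' @export
step_activation <- function(state, params, dt) {
  stopifnot(inherits(state, "t6_reactors"), inherits(params, "t6_kinetics"),
            dt > 0)
  if (is.finite(params$lambda_plus) && params$lambda_plus * dt > 0.1)
    stop("lambda_plus * dt exceeds 0.1; reduce dt (tau-leap validity)")
  if (state$t >= params$tau_plus - 1e-12 && params$lambda_plus > 0) {
    idx <- which(!state$G)
    if (length(idx))
      state$G[idx] <- runif(length(idx)) < 1 - exp(-params$lambda_plus * dt)
  }
  state$t <- state$t + dt
  state
}

#' Advance the sheath assembly/firing stage by one time step
#'
#' Tau-leap update of the immigration--death process, applied only to
#' activated reactors: each existing sheath fires independently with
#' probability `1 - exp(-lambda_f * dt)`, then at most one synthesis event
#' occurs with probability `lambda_s * dt` (keeping the expected synthesis
#' rate exact), and a sheath born within the step is exposed to half a step
#' of firing. This midpoint exposure makes the stationary mean accurate to
#' second order in `dt`. The number fired is returned so a caller can
#' resolve the shots against neighbours. Requires `lambda_s * dt <= 0.1`
#' and `lambda_f * dt <= 0.1`.
#'
#' @inheritParams step_activation
#' @return A list with the updated `state` and an integer vector `fired`.
#' @export
step_sheath_dynamics <- function(state, params, dt) {
  stopifnot(inherits(state, "t6_reactors"), inherits(params, "t6_kinetics"),
            dt > 0)
  if (any(state$N < 0)) stop("negative sheath counts are invalid")
  if (params$lambda_s * dt > 0.1 || params$lambda_f * dt > 0.1)
    stop("lambda_s * dt or lambda_f * dt exceeds 0.1; reduce dt")
  res <- sheath_leap_cpp(as.integer(state$N), state$G,
                         params$lambda_s, params$lambda_f, dt)
  state$N <- res$N
  list(state = state, fired = res$fired)
}

#' Exact stochastic simulation of a reactor ensemble
#'
#' Event-driven (Gillespie) simulation of the full two-stage process for `n`
#' independent reactors up to time `t_end`. Unlike the tau-leap steppers,
#' this has no time-discretisation error and serves as the reference
#' implementation the steppers are validated against.
#'
#' @inheritParams reactor_state
#' @param t_end End time in hours.
#' @return A list with integer vector `N` and logical vector `G` at `t_end`.
#' @export
ssa_ensemble <- function(n, params, t_end, init_n = c("zero", "steady")) {
  stopifnot(inherits(params, "t6_kinetics"), n >= 1, t_end >= 0)
  init_n <- match.arg(init_n)
  ssa_ensemble_cpp(as.integer(n), params$p0, params$tau_plus,
                   params$lambda_plus, params$lambda_s, params$lambda_f,
                   t_end, if (init_n == "steady") 1L else 0L)
}

#' Transient sheath-number distribution from the master equation
#'
#' Numerically integrates the chemical master equation of the joint `(G, N)`
#' process. The initial condition places a fraction `p0` of reactors in the
#' activated state (with `N` given by `init_n`) and the rest inactive with
#' `N = 0`; inactive reactors hold `N` constant and flow into the activated
#' `N = 0` state at rate `lambda_plus` once `tau_plus` has elapsed. The state
#' space is truncated at `n_max`; with the default truncation the neglected
#' tail mass is far below the integration tolerance, and a truncation error
#' is raised if probability visibly accumulates in the last bin.
#'
#' @inheritParams reactor_state
#' @param t Time at which to evaluate the distribution (hours, >= 0).
#' @param n_max Truncation: the returned vector covers `N = 0..n_max`.
#'   Defaults to `ceiling(m + 10 * sqrt(m) + 10)` with `m = lambda_s /
#'   lambda_f` (or `m = lambda_s * t` when `lambda_f = 0`).
#' @return A probability vector over `N = 0..n_max`, summing to 1 within
#'   `1e-8`, marginalised over the activation state.
#' @export
transient_pmf <- function(params, t, n_max = NULL,
                          init_n = c("zero", "steady")) {
  stopifnot(inherits(params, "t6_kinetics"), t >= 0)
  init_n <- match.arg(init_n)
  ls <- params$lambda_s; lf <- params$lambda_f
  lp <- params$lambda_plus; tau <- params$tau_plus; p0 <- params$p0
  if (is.null(n_max)) {
    m <- if (lf > 0) ls / lf else ls * max(t, 1)
    n_max <- ceiling(m + 10 * sqrt(max(m, 1)) + 10)
  }
  n_max <- as.integer(n_max)
  if (n_max < 1) stop("n_max must be at least 1")

  p_act <- numeric(n_max + 1)
  if (init_n == "steady" && lf > 0) {
    p_act <- p0 * dpois(0:n_max, ls / lf)
  } else {
    p_act[1] <- p0
  }
  y0 <- c(u = 1 - p0, p_act)

  deriv <- function(tt, y, parms) {
    u <- y[1]
    p <- y[-1]
    k <- length(p) - 1
    nvec <- 0:k
    act <- parms$act
    du <- -act * u
    dp <- -(ls + lf * nvec) * p
    dp[k + 1] <- dp[k + 1] + ls * p[k + 1]  # no synthesis out of the last bin
    dp[-1] <- dp[-1] + ls * p[-(k + 1)]
    dp[-(k + 1)] <- dp[-(k + 1)] + lf * nvec[-1] * p[-1]
    dp[1] <- dp[1] + act * u
    list(c(du, dp))
  }
  integrate_leg <- function(y, from, to, act) {
    if (to <= from) return(y)
    sol <- deSolve::ode(y = y, times = c(from, to), func = deriv,
                        parms = list(act = act), method = "lsoda",
                        rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
    unname(sol[nrow(sol), -1])
  }
  # the activation rate switches on at tau_plus; integrate the two legs
  # separately so the solver never steps across the discontinuity
  y <- y0
  y <- integrate_leg(y, 0, min(tau, t), act = 0)
  if (!is.finite(lp) && t >= tau) {
    # instantaneous switching: all inactive mass moves to (G+, N = 0) at tau
    y[2] <- y[2] + y[1]
    y[1] <- 0
    y <- integrate_leg(y, min(tau, t), t, act = 0)
  } else {
    y <- integrate_leg(y, min(tau, t), t, act = lp)
  }
  pmf <- y[-1]
  pmf[1] <- pmf[1] + y[1]  # inactive reactors all carry N = 0
  pmf <- pmax(pmf, 0)
  if (pmf[n_max + 1] > 1e-10)
    stop("probability mass reached the truncation bin; increase n_max")
  unname(pmf)
}
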