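#' Fit the delayed-exponential activation curve to observed fractions
#'
#' Estimates `(p0, tau_plus, lambda_plus)` from a time series of activated
#' population fractions. Following the estimation protocol for the
#' surface-activation assays, `p0` is fixed to the mean of the two earliest
#' observations (the curve is flat during the waiting period), and
#' `(tau_plus, lambda_plus)` then minimise the sum of squared residuals of
#' the closed-form curve over all points, subject to `tau_plus >= 0` and
#' `lambda_plus >= 0`.
#'
#' The objective is non-smooth in `tau_plus` (kinks wherever `tau_plus`
#' crosses an observation time), so the minimisation is multi-started from a
#' 20 x 20 grid over `tau_plus` in `[0, max(times)]` and `lambda_plus` in
#' `[0, 5]` per hour, with the best starts refined by bounded
#' quasi-Newton iterations.
#'
#' @param series A data frame with columns `time_h` and `fraction` (and
#'   optionally `n_cells`), e.g. from [make_activation_series()] or
#'   [read_activation_series()]. At least 4 time points are required and
#'   times must be strictly increasing.
#' @return An object of class `t6_activation_fit`: a list with the fitted
#'   [kinetic_params()] (`params`; sheath rates zero), `p0`, `tau_plus`,
#'   `lambda_plus`, the residual sum of squares `ssr`, and `fitted` values.
#'
#' @examples
#' kp <- kinetic_params(p0 = 0.10, tau_plus = 1.34, lambda_plus = 0.118)
#' ts <- seq(0.5, 3, by = 0.5)
#' series <- data.frame(time_h = ts, fraction = activation_probability(kp, ts))
#' fit_activation_curve(series)
#' @export
fit_activation_curve <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "fraction") %in% names(series)))
  times <- as.numeric(series$time_h)
  frac <- as.numeric(series$fraction)
  if (length(times) < 4) stop("at least 4 time points are required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")

  p0 <- mean(frac[1:2])
  model <- function(tau, lam, t) {
    dt <- t - tau
    d <- exp(-dt * lam)
    d[dt == 0] <- 1
    ifelse(dt < 0, p0, p0 + (1 - p0) * (1 - d))
  }
  ssr_fun <- function(par) {
    r <- frac - model(par[1], par[2], times)
    sum(r * r)
  }

  tau_grid <- seq(0, max(times), length.out = 20)
  lam_grid <- seq(0, 5, length.out = 20)
  grid <- expand.grid(tau = tau_grid, lam = lam_grid)
  grid_ssr <- vapply(seq_len(nrow(grid)),
                     function(i) ssr_fun(c(grid$tau[i], grid$lam[i])),
                     numeric(1))
  starts <- grid[order(grid_ssr)[1:3], , drop = FALSE]

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(starts$tau[i], starts$lam[i]), ssr_fun, method = "L-BFGS-B",
            lower = c(0, 0), upper = c(max(times), Inf),
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  # polish with a derivative-free pass (the kink in tau can stall L-BFGS-B)
  polish <- optim(best$par, ssr_fun, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 2000))
  if (polish$value < best$value) best <- polish
  tau_hat <- max(0, min(best$par[1], max(times)))
  lam_hat <- max(0, best$par[2])

  structure(list(
    params = kinetic_params(p0 = min(max(p0, 0), 1), tau_plus = tau_hat,
                            lambda_plus = lam_hat),
    p0 = p0, tau_plus = tau_hat, lambda_plus = lam_hat,
    ssr = ssr_fun(c(tau_hat, lam_hat)),
    fitted = model(tau_hat, lam_hat, times),
    times = times, observed = frac), class = "t6_activation_fit")
}

#' @export
print.t6_activation_fit <- function(x, ...) {
  cat(sprintf(
    "Activation-curve fit: p0 = %.4g, tau+ = %.4g h, lambda+ = %.4g /h (SSR %.3g)\n",
    x$p0, x$tau_plus, x$lambda_plus, x$ssr))
  invisible(x)
}

#' Exponential-decay fit of a declining count series
#'
#' Fits `a * exp(-b * t)` to counts by least squares on the log scale,
#' restricted to times `t >= t_min`. Used for target-strain census curves,
#' where the early points reflect the liquid-to-surface transition rather
#' than killing and are excluded (default window starts at 2 h).
#'
#' @param times Observation times (hours).
#' @param counts Observed counts (must be positive within the fit window).
#' @param t_min Left edge of the fit window (hours).
#' @return An object of class `t6_decay_fit`: list with amplitude `a`,
#'   decay rate `b` (per hour), `t_min`, and the number of points used.
#' @export
fit_exponential_decay <- function(times, counts, t_min = 2) {
  stopifnot(length(times) == length(counts))
  keep <- times >= t_min
  if (sum(keep) < 2) stop("need at least 2 points with t >= t_min")
  if (any(counts[keep] <= 0))
    stop("counts in the fit window must be positive")
  fit <- lm(log(counts[keep]) ~ times[keep])
  structure(list(a = exp(unname(coef(fit)[1])), b = -unname(coef(fit)[2]),
                 t_min = t_min, n_used = sum(keep)),
            class = "t6_decay_fit")
}

#' @export
print.t6_decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit: a = %.4g, b = %.4g /h (t >= %g h, n = %d)\n",
              x$a, x$b, x$t_min, x$n_used))
  invisible(x)
}
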