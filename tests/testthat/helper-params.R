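# shared fixtures: the fitted surface-activation triples and the simulated
# strain parameter sets used across tests
kp_es401_fit <- kinetic_params(p0 = 0.10, tau_plus = 1.34,
                               lambda_plus = 0.118)
kp_fqa002_fit <- kinetic_params(p0 = 0.05, tau_plus = 1,
                                lambda_plus = 0.05)
kp_sheath <- kinetic_params(p0 = 1, tau_plus = 0, lambda_plus = 0,
                            lambda_s = 21, lambda_f = 6)

small_arena <- function(L = 40, boundary = "periodic")
  arena(L, boundary = boundary)

# a quick two-strain scenario on a small domain for engine-level tests
quick_duel <- function(L = 50, t_end = 3, seed = 1, primed = FALSE,
                       s1 = strain_es401(), s2 = strain_fqa002(), ...) {
  scenario_config(arena(L), list(s1, s2), primed = primed, t_end = t_end,
                  seed = seed, ...)
}

# closed-form activated fraction, written independently of the package
eq2_oracle <- function(p0, tau, lam, t)
  ifelse(t < tau, p0, p0 + (1 - p0) * (1 - exp(-(t - tau) * lam)))
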