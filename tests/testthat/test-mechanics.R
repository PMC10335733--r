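test_that("segment distance handles canonical configurations", {
  # parallel unit segments offset laterally
  d <- segment_min_distance(c(0, 0), c(1, 0), c(0, 0.7), c(1, 0.7))
  expect_equal(d$distance, 0.7)
  # crossing segments touch
  d <- segment_min_distance(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  expect_equal(d$distance, 0)
  # point-like degenerate segments
  d <- segment_min_distance(c(0, 0), c(0, 0), c(3, 4), c(3, 4))
  expect_equal(d$distance, 5)
})

test_that("segment distance agrees with a dense-sampling oracle", {
  set.seed(101)
  for (i in 1:150) {
    a1 <- runif(2, 0, 10); a2 <- a1 + runif(2, -3, 3)
    b1 <- runif(2, 0, 10); b2 <- b1 + runif(2, -3, 3)
    d <- segment_min_distance(a1, a2, b1, b2)$distance
    expect_lt(abs(d - seg_dist_oracle(a1, a2, b1, b2)), 1e-3)
  }
})

test_that("periodic segment distance uses the minimum image", {
  ar <- arena(10)
  # segments hugging opposite edges: wrapped gap is 1, unwrapped 8
  d <- segment_min_distance(c(0.5, 0), c(0.5, 1), c(9.5, 0), c(9.5, 1), ar)
  expect_equal(d$distance, 1)
  # and the same points without an arena give the unwrapped distance
  d2 <- segment_min_distance(c(0.5, 0), c(0.5, 1), c(9.5, 0), c(9.5, 1))
  expect_equal(d2$distance, 9)
})

test_that("effective growth rate applies the linear production cost", {
  mk <- function(r0, c, ls) strain_spec("s", kinetic_params(0, 0, 0, ls, 0),
                                        r0 = r0, c = c)
  expect_equal(effective_growth_rate(mk(1, 0, 21)), 1)
  expect_equal(effective_growth_rate(mk(1, 1 / 20, 20)), 0)  # maximal cost
  expect_equal(effective_growth_rate(mk(1, 0.025, 20)), 0.5)
  expect_equal(effective_growth_rate(mk(0.5, 1, 21)), 0)     # clamped at 0
})

test_that("growth is exactly exponential for an isolated unconstrained cell", {
  s <- strain_spec("g", kinetic_params(0, 0, 0, 0, 0), r0 = log(2))
  cells <- new_cells(x = 5, y = 5, ell = 2, radius = 0.5, G = TRUE)
  # one hour in many small steps: total length doubles exactly
  for (i in 1:1000) cells <- grow_cell(cells, list(s), 1 / 1000)
  expect_equal(cells$ell + 1, 6, tolerance = 1e-6)
  expect_equal(cells$added, 3, tolerance = 1e-6)
  # attenuation zero freezes the cell
  c2 <- grow_cell(new_cells(5, 5, ell = 2), list(s), 1, attenuation = 0)
  expect_equal(c2$ell, 2)
  # lysing cells never grow
  c3 <- new_cells(5, 5, ell = 2, G = TRUE)
  c3$status <- "lysing"
  expect_equal(grow_cell(c3, list(s), 1)$ell, 2)
})

test_that("growth attenuation combines pressure and carrying capacity", {
  ar <- arena(50)   # pressure_star = 1, carrying_capacity = 0.8
  expect_equal(growth_attenuation(0, 0, ar), 1)
  expect_equal(growth_attenuation(0, 0.8, ar), 0)
  expect_equal(growth_attenuation(0.5, 0, ar), 0.5)
  expect_equal(growth_attenuation(2, 0, ar), 0)
  expect_equal(growth_attenuation(0.5, 0.4, ar), 0.25)
})

test_that("division obeys the adder rule and conserves sheaths", {
  cells <- new_cells(x = c(1, 5), y = 2, theta = 0, ell = c(3, 3),
                     radius = 0.5, N = c(7L, 7L))
  cells$added <- c(2.1, 1.0)   # only the first has completed its adder
  set.seed(3)
  out <- maybe_divide(cells, delta_L = 2)
  expect_equal(nrow(out), 3)
  d <- out[out$id != 2, ]
  expect_equal(d$ell, rep(1, 2))            # (3 - 1) / 2 each
  expect_equal(sum(d$N), 7)                 # sheaths conserved exactly
  expect_equal(d$added, rep(0, 2))
  # daughters sit end-to-end across the mother's extent
  expect_equal(sort(d$x), c(0, 2), tolerance = 1e-12)
  # total cylinder length change is bounded by the cap geometry
  expect_lt(abs(sum(d$ell) - 3), 2 * 0.5 + 1e-12)
  # untriggered cell untouched
  expect_equal(out$ell[out$id == 2], 3)
})

test_that("sheath partition at division is Binomial(N, 1/2)", {
  set.seed(8)
  n <- 1e5
  cells <- new_cells(x = seq_len(n) * 10, y = 0, ell = 3, radius = 0.5,
                     N = 10L)
  cells$added <- 2.5
  out <- maybe_divide(cells, delta_L = 2)
  first <- out$N[seq_len(n)]
  expect_equal(out$N[order(out$id)] |> sum(), 10L * n)  # exact conservation
  se_mean <- sqrt(2.5 / n)
  expect_lt(abs(mean(first) - 5), 3 * se_mean)
  expect_lt(abs(var(first) - 2.5), 0.1)
})

test_that("pair interaction is Hookean, symmetric and zero out of contact", {
  ar <- arena(50)
  a <- new_cells(x = 10, y = 10, theta = 0, ell = 2)
  b <- new_cells(x = 10, y = 10.7, theta = 0, ell = 2)
  res <- pair_interaction(a, b, ar)
  expect_equal(res$overlap, 0.3)
  expect_equal(res$force_a, c(0, -20 * 0.3))  # pushed apart along -y
  expect_equal(res$force_a + res$force_b, c(0, 0))
  far <- new_cells(x = 20, y = 40, theta = 1, ell = 2)
  res2 <- pair_interaction(a, far, ar)
  expect_equal(res2$force_a, c(0, 0))
  expect_equal(res2$overlap, 0)
})

test_that("mechanics relaxes overlap symmetrically and conserves drag momentum", {
  ar <- arena(50)
  cells <- new_cells(x = c(25, 25), y = c(24.7, 25.4), theta = 0, ell = 2)
  for (i in 1:600) cells <- step_mechanics(cells, ar)
  gap <- abs(diff(cells$y))
  expect_lt(abs(gap - 1), 1e-3 * 0.5)         # overlap resolved
  expect_equal(sum(cells$y), 24.7 + 25.4, tolerance = 1e-9)  # symmetric push
  # isolated cell does not move
  solo <- new_cells(x = 10, y = 10, theta = 0.3, ell = 2)
  expect_equal(step_mechanics(solo, ar), solo)
})

test_that("drag-weighted displacement sums to zero for internal forces", {
  set.seed(21)
  ar <- arena(30)
  cells <- make_toy_population(120, ar)
  # shrink the box artificially by inflating lengths to force overlaps
  cells$ell <- cells$ell * 1.6
  moved <- step_mechanics(cells, ar)
  w <- (cells$ell + 2 * cells$radius) * ar$mech$zeta
  expect_equal(sum(w * (moved$x - cells$x)), 0, tolerance = 1e-9)
  expect_equal(sum(w * (moved$y - cells$y)), 0, tolerance = 1e-9)
})

test_that("forces are invariant under lattice translations of all cells", {
  set.seed(22)
  ar <- arena(30)
  cells <- make_toy_population(80, ar)
  cells$ell <- cells$ell * 1.5
  m1 <- step_mechanics(cells, ar)
  shifted <- cells
  shifted$x <- (cells$x + ar$Lx) %% ar$Lx
  shifted$y <- (cells$y + 2 * ar$Ly) %% ar$Ly
  m2 <- step_mechanics(shifted, ar)
  expect_equal(m2$x, m1$x, tolerance = 1e-10)
  expect_equal(m2$theta, m1$theta, tolerance = 1e-10)
})

test_that("non-interpenetration holds at quasi-equilibrium", {
  set.seed(23)
  ar <- arena(25)
  cells <- make_toy_population(100, ar)
  cells$ell <- cells$ell * 1.4   # induce overlaps
  for (i in 1:800) cells <- step_mechanics(cells, ar)
  pr <- build_contacts(cells, ar)$pairs
  if (nrow(pr)) expect_lt(max(-pr[, "gap"], 0), 1e-2 * 0.5)
})

test_that("unstable sub-steps are rejected", {
  ar <- arena(50)
  expect_error(step_mechanics(make_toy_population(10, ar), ar,
                              dt_mech = 0.05), "stability")
})
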