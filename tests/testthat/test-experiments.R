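test_that("outcome statistic phi and lethality beta follow their definitions", {
  expect_equal(competition_outcome(500, 0), 1)
  expect_equal(competition_outcome(0, 500), -1)
  expect_equal(competition_outcome(123, 123), 0)
  expect_error(competition_outcome(0, 0), "undefined")
  expect_equal(lethality_beta(20, 20), 0.5)
  expect_equal(lethality_beta(0, 20), 0)
  expect_equal(lethality_beta(10, 20), 1 / 3)
  expect_error(lethality_beta(0, 0), "undefined")
})

test_that("seeding respects priming, p0 and the steady-state sheath load", {
  cfg <- quick_duel(L = 120, seed = 1, primed = TRUE)
  set.seed(2)
  cells <- seed_coincubation(cfg)
  expect_true(all(cells$G))
  expect_lt(abs(mean(cells$N) - 3.5), 4 * sqrt(3.5 / nrow(cells)))
  # unprimed: activation is Bernoulli(p0) per strain, inactive carry no sheaths
  cfg2 <- quick_duel(L = 200, seed = 1, primed = FALSE)
  set.seed(3)
  cells2 <- seed_coincubation(cfg2)
  for (s in 1:2) {
    sub <- cells2[cells2$strain == s, ]
    p0 <- cfg2$strains[[s]]$kinetics$p0
    expect_lt(abs(mean(sub$G) - p0), 3 * sqrt(p0 * (1 - p0) / nrow(sub)))
  }
  expect_true(all(cells2$N[!cells2$G] == 0))
  expect_gt(mean(cells2$N[cells2$G]), 0)
  # placements never overlap and lie in the arena
  pr <- build_contacts(cells2, cfg2$arena)$pairs
  if (nrow(pr)) expect_true(all(pr[, "gap"] > 0))
  expect_true(all(cells2$x >= 0 & cells2$x <= 200))
  # mix ratio is honoured
  expect_equal(abs(diff(table(cells2$strain))) < 2, TRUE,
               ignore_attr = TRUE)
})

test_that("area occupancy fractions are correct and sum to one", {
  cells <- new_cells(x = c(10, 20), y = 10, ell = 2, strain = 1:2)
  af <- area_occupancy(cells, c(0, 40, 0, 40))
  expect_equal(unname(af), c(0.5, 0.5))
  expect_equal(sum(af), 1)
  # single strain fills the window
  solo <- new_cells(x = 10, y = 10, ell = 3)
  expect_equal(unname(area_occupancy(solo, c(0, 40, 0, 40))), 1)
  # lysing cells and cells outside the window are excluded
  cells$status[2] <- "lysing"
  af2 <- area_occupancy(cells, c(0, 40, 0, 40))
  expect_equal(unname(af2), c(1, 0))
  expect_error(area_occupancy(cells[cells$status != "alive", ],
                              c(0, 40, 0, 40)), "undefined")
})

test_that("area occupancy matches a rasterisation oracle", {
  set.seed(91)
  ar <- arena(30)
  cells <- make_toy_population(40, ar, strain = rep(1:2, each = 20))
  win <- c(5, 25, 5, 25)
  af <- area_occupancy(cells, win)
  areas <- vapply(seq_len(nrow(cells)),
                  function(i) capsule_pixel_area(cells[i, ]), numeric(1))
  inw <- cells$x >= win[1] & cells$x <= win[2] &
    cells$y >= win[3] & cells$y <= win[4]
  oracle <- tapply(areas[inw], cells$strain[inw], sum)
  oracle <- oracle / sum(oracle)
  expect_lt(max(abs(af - oracle)), 0.01)
})

test_that("runs are deterministic given the master seed", {
  cfg <- quick_duel(L = 40, t_end = 2, seed = 314)
  a <- run_competition(cfg)
  b <- run_competition(cfg)
  expect_identical(a$replicates[[1]]$series, b$replicates[[1]]$series)
  expect_identical(a$replicates[[1]]$cells, b$replicates[[1]]$cells)
  expect_identical(a$phi, b$phi)
  # a different seed gives a different trajectory
  cfg2 <- quick_duel(L = 40, t_end = 2, seed = 315)
  d <- run_competition(cfg2)
  expect_false(identical(d$replicates[[1]]$cells, a$replicates[[1]]$cells))
})

test_that("population bookkeeping balances births, kills and removals", {
  cfg <- quick_duel(L = 50, t_end = 5, seed = 77, primed = TRUE)
  r <- run_competition(cfg)$replicates[[1]]
  n_final <- nrow(r$cells)
  expect_equal(n_final, cfg$n_init + r$births - r$removed)
  # lysing cells in the final state are part of the kill count
  expect_gte(sum(r$kills), r$removed)
  expect_equal(sum(r$kills) - r$removed,
               sum(r$cells$status == "lysing"))
})

test_that("phi is antisymmetric under strain relabelling (in distribution)", {
  cfg <- quick_duel(L = 60, t_end = 6, seed = 5, primed = TRUE,
                    n_replicates = 6)
  fwd <- run_competition(cfg)
  cfg_sw <- quick_duel(L = 60, t_end = 6, seed = 5, primed = TRUE,
                       s1 = strain_fqa002(), s2 = strain_es401(),
                       n_replicates = 6)
  rev <- run_competition(cfg_sw)
  se <- sqrt(sd(fwd$phi)^2 / 6 + sd(rev$phi)^2 / 6)
  expect_lt(abs(mean(fwd$phi) + mean(rev$phi)), 4 * se + 0.05)
  expect_true(all(abs(c(fwd$phi, rev$phi)) <= 1))
})

test_that("a lethal strain with no sheath production cannot suppress the target", {
  # lambda_s = 0: the armed strain never builds a weapon, target grows freely
  disarmed <- strain_spec("armed0",
                          kinetic_params(0.1, 1, 0.6, 0, 6), r0 = 1)
  target <- strain_es401(vasA = TRUE)
  cfg <- scenario_config(arena(50), list(disarmed, target), t_end = 6,
                         seed = 8)
  out <- run_target_elimination(cfg)
  expect_equal(out$target, "ES401_vasA")
  counts <- out$series$target_mean
  expect_true(all(diff(counts) >= 0))   # never declines without weapons
  expect_equal(unname(out$competition$replicates[[1]]$kills), c(0, 0))
})

test_that("target elimination requires exactly one armed strain", {
  cfg <- quick_duel(L = 40, t_end = 1)
  expect_error(run_target_elimination(cfg), "exactly one")
})

test_that("unarmed targets survive at the edge of a range expansion", {
  cfg <- scenario_config(arena(260, boundary = "open"),
                         list(strain_es401(), strain_fqa002(vasA = TRUE)),
                         inoculum_radius = 15, t_end = 7, seed = 42,
                         measure_window = c(80, 180, 80, 180))
  rx <- run_range_expansion(cfg)
  expect_gt(rx$colony_radius[1], 15)      # the colony expanded
  surv <- rx$census[rx$census$strain == "FQA002_vasA", ]
  expect_gt(nrow(surv), 0)                # some targets persist
  # survivors concentrate at the expanding edge
  expect_gt(mean(surv$radius_um), rx$colony_radius[1] / 2)
  # a clonal inoculum's census is the whole population
  solo <- scenario_config(arena(200, boundary = "open"),
                          list(strain_es401()), inoculum_radius = 12,
                          t_end = 3, seed = 2,
                          measure_window = c(50, 150, 50, 150))
  rs <- run_range_expansion(solo)
  expect_equal(nrow(rs$census),
               sum(rs$competition$replicates[[1]]$cells$status == "alive"))
})

test_that("range expansion rejects inconsistent configurations", {
  cfg <- quick_duel(L = 40, t_end = 1)
  expect_error(run_range_expansion(cfg), "open")
})
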