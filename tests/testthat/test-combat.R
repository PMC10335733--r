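test_that("contact graph matches a brute-force all-pairs check", {
  set.seed(55)
  ar <- arena(20)
  cells <- make_toy_population(60, ar)
  cells$ell <- cells$ell * 1.3
  g <- build_contacts(cells, ar)
  eps <- ar$mech$contact_eps
  ends <- function(i) {
    h <- cells$ell[i] / 2
    list(p1 = c(cells$x[i] - h * cos(cells$theta[i]),
                cells$y[i] - h * sin(cells$theta[i])),
         p2 = c(cells$x[i] + h * cos(cells$theta[i]),
                cells$y[i] + h * sin(cells$theta[i])))
  }
  for (i in seq_len(nrow(cells))) {
    nb <- integer(0)
    for (j in seq_len(nrow(cells))) {
      if (i == j) next
      ei <- ends(i); ej <- ends(j)
      d <- segment_min_distance(ei$p1, ei$p2, ej$p1, ej$p2, ar)$distance
      if (d - 2 * cells$radius[1] <= eps) nb <- c(nb, j)
    }
    expect_setequal(g$adjacency[[i]], nb)
  }
  # symmetry and no self-contacts
  for (i in seq_len(nrow(cells))) {
    expect_false(i %in% g$adjacency[[i]])
    for (j in g$adjacency[[i]]) expect_true(i %in% g$adjacency[[j]])
  }
})

test_that("firing with no contacts always misses", {
  ar <- arena(30)
  cells <- new_cells(x = c(5, 25), y = c(5, 25), ell = 2,
                     strain = c(1L, 2L), G = TRUE, N = 5L)
  g <- build_contacts(cells, ar)
  strains <- list(strain_es401(), strain_fqa002())
  set.seed(1)
  out <- resolve_firing(cells, 1, 50, g, strains)
  expect_true(all(out$outcomes$result == "miss"))
  expect_true(all(out$cells$status == "alive"))
})

test_that("clonemates are immune and corpses absorb hits", {
  ar <- arena(10)
  cells <- new_cells(x = c(5, 5.9, 4.1), y = 5, theta = pi / 2, ell = 2,
                     strain = c(1L, 1L, 2L), G = TRUE, N = 10L)
  strains <- list(strain_es401(), strain_fqa002())
  g <- build_contacts(cells, ar)
  set.seed(2)
  out <- resolve_firing(cells, 1, 200, g, strains, k_max = 2)
  hits_clone <- out$outcomes$result[out$outcomes$target_id == 2]
  expect_true(all(hits_clone == "hit_clonemate"))
  expect_equal(out$cells$status[2], "alive")
  # the enemy neighbour was killed by the first hit, later hits absorbed
  enemy <- out$outcomes$result[out$outcomes$target_id == 3]
  expect_equal(sum(enemy == "kill"), 1)
  expect_equal(enemy[enemy != "kill"],
               rep("hit_dead", length(enemy) - 1))
  expect_equal(out$cells$status[3], "lysing")
  expect_equal(out$cells$lysis_clock[3], 0.5)
})

test_that("slot model hits contacts in proportion k / k_max", {
  ar <- arena(10)
  # shooter with 3 contacts and k_max = 6: hit probability 1/2 per shot
  cells <- new_cells(x = c(5, 5.9, 4.1, 5), y = c(5, 5, 5, 5.9),
                     theta = pi / 2, ell = 0.8,
                     strain = c(1L, 2L, 2L, 2L), G = TRUE, N = 0L)
  strains <- list(strain_spec("a", kinetic_params(), r0 = 1, tau_lys = 1e6),
                  strain_spec("b", kinetic_params(), r0 = 1, tau_lys = 1e6))
  g <- build_contacts(cells, ar)
  expect_equal(sort(g$adjacency[[1]]), c(2, 3, 4))
  set.seed(4)
  n_shots <- 1e5
  out <- resolve_firing(cells, 1, n_shots, g, strains, k_max = 6)
  hit_frac <- mean(out$outcomes$result != "miss")
  expect_lt(abs(hit_frac - 0.5), 3 * sqrt(0.25 / n_shots))
  # k >= k_max: every shot lands on a contact
  out2 <- resolve_firing(cells, 1, 2000, g, strains, k_max = 3)
  expect_true(all(out2$outcomes$result != "miss"))
  # k_max = Inf also never misses when contacts exist
  out3 <- resolve_firing(cells, 1, 2000, g, strains, k_max = Inf)
  expect_true(all(out3$outcomes$result != "miss"))
})

test_that("miss probability is non-increasing in the number of contacts", {
  k_max <- 6
  miss_prob <- function(k) max(0, (k_max - k)) / max(k, k_max)
  probs <- vapply(0:10, miss_prob, numeric(1))
  expect_true(all(diff(probs) <= 0))
  expect_equal(probs[1], 1)
  expect_true(all(probs[(k_max + 1):11] == 0))
})

test_that("lysis lifecycle removes corpses only after tau_lys", {
  cells <- new_cells(x = c(1, 2), y = 1, ell = 2, strain = 1:2)
  cells$status[1] <- "lysing"
  cells$lysis_clock[1] <- 0.5
  # still present up to just before tau_lys has elapsed
  c1 <- update_lysis(cells, 0.49)
  expect_equal(nrow(c1), 2)
  expect_equal(c1$lysis_clock[1], 0.01, tolerance = 1e-12)
  c2 <- update_lysis(c1, 0.01)
  expect_equal(nrow(c2), 1)
  expect_equal(c2$id, 2)
  # tau_lys = 0 disappears in the same step
  cells$lysis_clock[1] <- 0
  expect_equal(nrow(update_lysis(cells, 0.001)), 1)
})

test_that("clonal populations never record a kill (engine-level immunity)", {
  # single-strain dense colony, everyone activated and firing from t = 0
  cfg <- scenario_config(arena(60), list(strain_es401()), primed = TRUE,
                         t_end = 8, seed = 99)
  res <- run_competition(cfg)
  r <- res$replicates[[1]]
  expect_equal(unname(r$kills), 0)
  expect_equal(r$removed, 0)
  expect_true(all(r$cells$status == "alive"))
})

test_that("strains that cannot fire never produce firing outcomes", {
  cfg <- scenario_config(arena(40),
                         list(strain_es401(vasA = TRUE),
                              strain_fqa002(vasA = TRUE)),
                         t_end = 6, seed = 12)
  res <- run_competition(cfg)
  expect_equal(unname(res$replicates[[1]]$kills), c(0, 0))
  expect_equal(res$replicates[[1]]$removed, 0)
})
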