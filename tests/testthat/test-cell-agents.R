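test_that("grid-based velocities equal the all-pairs force law", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- 40
    pos <- cbind(runif(n, 0, 120), runif(n, 0, 120), runif(n, 0, 40))
    rad <- runif(n, 5, 10)
    got <- compute_velocities(pos, rad)
    want <- brute_force_velocities(pos, rad)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("isolated, overlapping and distant cells behave per the force law", {
  # single isolated non-motile cell: zero velocity
  expect_equal(compute_velocities(matrix(c(0, 0, 0), 1), 8),
               matrix(0, 1, 3))

  # two identical overlapping cells: equal magnitude, opposite direction
  pos <- rbind(c(0, 0, 0), c(5, 0, 0))
  v <- compute_velocities(pos, c(8, 8))
  expect_equal(v[1, ], -v[2, ])
  expect_lt(v[1, 1], 0) # net repulsion when overlapping
  expect_equal(colSums(v), c(0, 0, 0)) # momentum-like symmetry

  # cells beyond the interaction range never interact
  pos2 <- rbind(c(0, 0, 0), c(500, 0, 0))
  expect_equal(compute_velocities(pos2, c(8, 8)), matrix(0, 2, 3))

  # coincident centers are pushed apart deterministically, no NaN
  pos3 <- rbind(c(1, 1, 0), c(1, 1, 0))
  v3a <- compute_velocities(pos3, c(8, 8), three_d = FALSE)
  v3b <- compute_velocities(pos3, c(8, 8), three_d = FALSE)
  expect_identical(v3a, v3b)
  expect_true(all(is.finite(v3a)))
  expect_gt(sum(v3a[1, ]^2), 0)
  expect_equal(v3a[1, ], -v3a[2, ])
})

test_that("attached pairs get boosted adhesion", {
  pos <- rbind(c(0, 0, 0), c(18, 0, 0)) # touching but not overlapping
  v0 <- compute_velocities(pos, c(8, 8))
  vb <- compute_velocities(pos, c(8, 8),
                           attached_pairs = matrix(c(1, 2), 1),
                           attachment_multiplier = 10)
  expect_equal(vb[1, 1], 10 * v0[1, 1], tolerance = 1e-12)
})

test_that("Adams-Bashforth position updates match the formula", {
  # constant velocity: displacement is exactly v * t
  pos <- matrix(c(0, 0, 0), 1)
  v <- matrix(c(2, -1, 0.5), 1)
  p <- pos; pv <- matrix(NA_real_, 1, 3)
  for (i in 1:10) {
    p <- update_positions(p, v, pv, dt = 0.1)
    pv <- v
  }
  expect_equal(as.numeric(p), c(2, -1, 0.5) * 1.0, tolerance = 1e-12)

  # zero velocity: unchanged
  expect_equal(update_positions(matrix(1:3, 1), matrix(0, 1, 3),
                                matrix(0, 1, 3), 5),
               matrix(as.numeric(1:3), 1))

  # alternating +u/-u: dt (1.5 v - 0.5 v_prev) = 2u dt
  u <- c(1, 2, 3)
  p2 <- update_positions(matrix(0, 1, 3), matrix(u, 1),
                         matrix(-u, 1), dt = 1)
  expect_equal(as.numeric(p2), 2 * u)
})

test_that("the oxygen-dependent cycle entry rate ramps and saturates", {
  # saturated at and above physioxia
  expect_equal(cycle_entry_rate(1, 38, 1e-3), 1e-3)
  expect_equal(cycle_entry_rate(1.4, 60, 1e-3), 1.4e-3)
  # zero max rate never divides
  expect_equal(cycle_entry_rate(1, 60, 0), 0)
  # exactly at the necrosis threshold the rate is zero
  expect_equal(cycle_entry_rate(1, 5, 1e-3), 0)
  # linear in between
  expect_equal(cycle_entry_rate(1, (5 + 38) / 2, 1e-3), 5e-4)
})

test_that("an empty simulation still runs and evolves its fields", {
  m <- create_mesh(10, 10, 1, origin = c(-100, -100, -10))
  s <- substrate_system("oxygen", D = 1e4, lambda = 0.1,
                        boundary = "dirichlet", boundary_value = 38,
                        initial = 0)
  cells <- init_heterogeneous_tumor(1)[0, ]
  cfg <- tissue_config(m, s, cells, duration = 60, save_interval = 30,
                       seed = 1)
  sim <- simulate_tissue(cfg)
  expect_equal(nrow(final_snapshot(sim)$cells), 0)
  # oxygen has diffused in from the boundary
  expect_gt(min(final_snapshot(sim)$fields), 1)
})

test_that("snapshot cadence counts the initial state", {
  m <- create_mesh(10, 10, 1, origin = c(-100, -100, -10))
  s <- substrate_system("oxygen", D = 1e5, lambda = 0.1,
                        boundary = "dirichlet", boundary_value = 38)
  set.seed(2)
  cells <- init_heterogeneous_tumor(10)
  cfg <- tissue_config(m, s, cells, duration = 60, save_interval = 3,
                       seed = 2)
  sim <- simulate_tissue(cfg)
  expect_length(sim$snapshots, 21)
  expect_equal(sim$snapshots[[1]]$time, 0)
  expect_equal(final_snapshot(sim)$time, 60)
})

test_that("identical configuration and seed give bit-identical output", {
  m <- create_mesh(20, 20, 1, origin = c(-200, -200, -10))
  s <- substrate_system("oxygen", D = 1e5, lambda = 0.1,
                        boundary = "dirichlet", boundary_value = 20)
  set.seed(9)
  cells <- init_heterogeneous_tumor(60)
  cfg <- tissue_config(m, s, cells, duration = 360, seed = 31)
  s1 <- simulate_tissue(cfg)
  s2 <- simulate_tissue(cfg)
  expect_identical(final_snapshot(s1)$cells, final_snapshot(s2)$cells)
  expect_identical(final_snapshot(s1)$fields, final_snapshot(s2)$fields)
})

test_that("cell counts satisfy the bookkeeping identity at every record", {
  m <- create_mesh(20, 20, 1, origin = c(-200, -200, -10))
  s <- substrate_system("oxygen", D = 1e5, lambda = 0.1,
                        boundary = "dirichlet", boundary_value = 8)
  set.seed(4)
  cells <- init_heterogeneous_tumor(150)
  cfg <- tissue_config(m, s, cells,
                       tumor = tumor_phenotype(apoptosis_rate = 2e-3),
                       duration = 720, seed = 5)
  sim <- simulate_tissue(cfg)
  ts <- sim$timeseries
  present <- ts$live_tumor + ts$apoptotic + ts$necrotic
  expect_equal(present, 150 + ts$divisions - ts$removed)
  expect_gt(ts$removed[nrow(ts)], 0) # apoptotic cells do get excised
})

test_that("division events follow the expected birth process", {
  # saturated oxygen, no death: a discrete-time branching process with
  # per-cell, per-phenotype-step division probability q = r * dt gives
  # E[N(T)] = (1 + q)^(T / dt)
  r <- 0.002; Tend <- 360; dtp <- 6
  m <- create_mesh(10, 10, 1, origin = c(-100, -100, -10))
  cells1 <- data.frame(kind = "tumor", x = 0, y = 0, z = 0, volume = 2494,
                       oncoprotein = 1)
  finals <- vapply(1:80, function(sd) {
    cfg <- tissue_config(m, NULL, cells1,
                         tumor = tumor_phenotype(cycle_entry_rate_max = r,
                                                 apoptosis_rate = 0,
                                                 volume_relax_rate = 0.2),
                         duration = Tend, oxygen = NULL, seed = sd)
    nrow(final_snapshot(simulate_tissue(cfg))$cells)
  }, numeric(1))
  expected <- (1 + r * dtp)^(Tend / dtp)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se + 1e-9)
})
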