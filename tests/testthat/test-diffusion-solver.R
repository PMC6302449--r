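test_that("bulk source/uptake follows the backward-Euler closed form", {
  m <- create_mesh(3, 3, 1)
  s <- substrate_system("o", D = 0, lambda = 0, bulk_S = 1, bulk_U = 0,
                        rho_star = 38)
  f <- new_field(m, s, values = 0)
  f1 <- step_bulk_supply(f, s, 0.01)
  expect_equal(as.numeric(f1), rep(0.38 / 1.01, 9), tolerance = 1e-12)

  # S = U = 0 is the identity
  s0 <- substrate_system("o", D = 0, lambda = 0)
  f <- new_field(m, s0, values = 3.7)
  expect_equal(as.numeric(step_bulk_supply(f, s0, 0.5)), rep(3.7, 9))

  # repeated stepping converges to the fixed point S rho* / (S + U)
  sf <- substrate_system("o", D = 0, lambda = 0, bulk_S = 0.5, bulk_U = 0.25,
                         rho_star = 38)
  f <- new_field(m, sf, values = 0)
  for (i in 1:4000) f <- step_bulk_supply(f, sf, 0.05)
  expect_equal(as.numeric(f)[1], 0.5 * 38 / 0.75, tolerance = 1e-8)
})

test_that("cell exchange updates only the containing voxel, scaled by W/V", {
  m <- create_mesh(5, 5, 1)
  s <- substrate_system("o", D = 0, lambda = 0)
  f <- new_field(m, s, values = 0)
  # one cell with W = voxel volume reduces to the bulk update in its voxel
  ex <- cell_exchange(id = 1, position = c(50, 50, 10),
                      volume = m$voxel_volume, S = 1, U = 0, rho_star = 38)
  f1 <- step_cell_exchange(f, m, ex, 0.01)
  v <- attr(voxel_containing(m, c(50, 50, 10)), "linear")
  expect_equal(as.numeric(f1[v, 1]), 0.38 / 1.01, tolerance = 1e-12)
  expect_equal(sum(f1[-v, 1]), 0)

  # no cells: unchanged
  f2 <- step_cell_exchange(f, m, cell_exchange(integer(0),
                                               matrix(0, 0, 3),
                                               numeric(0), 1, 1, 1, m = 1),
                           0.01)
  expect_equal(as.numeric(f2), as.numeric(f))

  # pure uptake decreases the voxel value but never below zero
  f3 <- new_field(m, s, values = 5)
  ex2 <- cell_exchange(id = 1, position = c(50, 50, 10), volume = 4000,
                       S = 0, U = 10, rho_star = 0)
  prev <- 5
  for (i in 1:200) {
    f3 <- step_cell_exchange(f3, m, ex2, 0.1)
    expect_lt(f3[v, 1], prev)
    expect_gte(f3[v, 1], 0)
    prev <- f3[v, 1]
  }

  expect_error(step_cell_exchange(f, m,
                                  cell_exchange(1, c(999, 0, 0), 100, 1, 0, 1),
                                  0.01),
               "outside the domain")
})

test_that("each axis solve equals a dense tridiagonal solve", {
  set.seed(7)
  for (n in c(5, 17, 32)) {
    vals <- runif(n, 0, 10)
    expected <- dense_axis_solve(vals, n, D = 1000, lambda = 0.1, dt = 0.01,
                                 h = 20)
    for (axis in 1:3) {
      dims <- c(1, 1, 1); dims[axis] <- n
      m <- create_mesh(dims[1], dims[2], dims[3])
      s <- substrate_system("o", D = 1000, lambda = 0.1)
      f <- new_field(m, s, values = matrix(vals, n, 1))
      got <- step_diffusion_decay(f, precompute_thomas(m, s, 0.01))
      expect_lt(max(abs(got[, 1] - expected) / pmax(abs(expected), 1e-300)),
                1e-12)
    }
  }
})

test_that("degenerate coefficients and cache reuse behave exactly", {
  m <- create_mesh(8, 6, 1)
  # D = 0, lambda = 0: the axis systems are the identity
  s0 <- substrate_system("o", D = 0, lambda = 0)
  set.seed(3)
  vals <- matrix(runif(48), 48, 1)
  f <- new_field(m, s0, values = vals)
  expect_equal(as.numeric(step_diffusion_decay(f, precompute_thomas(m, s0, 0.01))),
               as.numeric(vals))

  # cache reuse is bit-identical to a fresh cache
  s <- substrate_system(c("a", "b"), D = c(800, 10), lambda = c(0.2, 0))
  f <- new_field(m, s, values = matrix(runif(96), 48, 2))
  cache <- precompute_thomas(m, s, 0.02)
  g1 <- f
  for (i in 1:5) g1 <- step_diffusion_decay(g1, cache)
  g2 <- f
  for (i in 1:5) g2 <- step_diffusion_decay(g2, precompute_thomas(m, s, 0.02))
  expect_identical(as.numeric(g1), as.numeric(g2))

  # stale cache is rejected
  m2 <- create_mesh(9, 6, 1)
  f2 <- new_field(m2, s)
  expect_error(step_diffusion_decay(f2, cache), "cache-invalid")
})

test_that("pure decay follows the per-axis implicit recurrence", {
  # 2-D mesh: lambda apportioned as lambda/2 per axis solve
  m <- create_mesh(6, 6, 1)
  s <- substrate_system("o", D = 0, lambda = 0.3)
  f <- new_field(m, s, values = 2)
  cache <- precompute_thomas(m, s, 0.05)
  nsteps <- 20
  for (i in 1:nsteps) f <- step_diffusion_decay(f, cache)
  expect_equal(as.numeric(f)[1],
               2 / (1 + 0.3 * 0.05 / 2)^(2 * nsteps), tolerance = 1e-12)
})

test_that("mass is conserved with no decay and no-flux boundaries", {
  m <- create_mesh(14, 11, 1)
  s <- substrate_system("o", D = 2000, lambda = 0)
  set.seed(5)
  f <- new_field(m, s, values = matrix(runif(154, 0, 10), 154, 1))
  cache <- precompute_thomas(m, s, 0.1)
  mass0 <- sum(f)
  for (i in 1:100) {
    f <- step_diffusion_decay(f, cache)
    expect_lt(abs(sum(f) - mass0) / mass0, 1e-10)
  }
  # nonnegativity with nonnegative data
  expect_true(all(f >= -1e-12))
})

test_that("a uniform field is steady and Dirichlet boundaries pin", {
  m <- create_mesh(10, 10, 1)
  s <- substrate_system("o", D = 5000, lambda = 0)
  f <- new_field(m, s, values = 4.2)
  f1 <- step_diffusion_decay(f, precompute_thomas(m, s, 0.01))
  expect_equal(as.numeric(f1), rep(4.2, 100), tolerance = 1e-14)

  sd_ <- substrate_system("o", D = 5000, lambda = 0, boundary = "dirichlet",
                          boundary_value = 38)
  f2 <- new_field(m, sd_, values = 0)
  f2 <- step_diffusion_decay(f2, precompute_thomas(m, sd_, 0.01))
  idx <- matrix(seq_len(100), 10, 10)
  boundary <- c(idx[1, ], idx[10, ], idx[, 1], idx[, 10])
  expect_true(all(f2[boundary, 1] == 38))
  expect_true(all(f2[-boundary, 1] < 38))
})

test_that("the operator-split step applies sub-steps in the stated order", {
  m <- create_mesh(3, 1, 1)
  # bulk uptake and a cell source in the same voxel do not commute
  s <- substrate_system("o", D = 0, lambda = 0, bulk_S = 0, bulk_U = 2,
                        rho_star = 0)
  f <- new_field(m, s, values = 10)
  ex <- cell_exchange(1, c(10, 10, 10), volume = 8000, S = 3, U = 0,
                      rho_star = 38)
  dt <- 0.5
  got <- diffusion_step(f, m, s, ex, dt)
  bulk_first <- (10 / (1 + dt * 2) + dt * 3 * 38) / (1 + dt * 3)
  cell_first <- ((10 + dt * 3 * 38) / (1 + dt * 3)) / (1 + dt * 2)
  expect_equal(as.numeric(got[1, 1]), bulk_first, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(as.numeric(got[1, 1]), cell_first)))

  # S = U = 0, no cells, uniform field: unchanged
  s0 <- substrate_system("o", D = 3000, lambda = 0)
  f0 <- new_field(m, s0, values = 1.5)
  expect_equal(as.numeric(diffusion_step(f0, m, s0, NULL, 0.01)),
               rep(1.5, 3), tolerance = 1e-14)
})

test_that("the solver tracks the decaying-sinusoid closed form and is
           stable far beyond the default step", {
  L <- 100; n <- 64; D <- 1000; lambda <- 0.1
  k <- pi / L
  m <- create_mesh(n, 1, 1, dx = L / n)
  s <- substrate_system("o", D = D, lambda = lambda)
  xc <- (seq_len(n) - 0.5) * L / n
  mu <- D * k^2 + lambda
  f <- new_field(m, s, values = matrix(2 + cos(k * xc), n, 1))
  dt <- 0.01; Tend <- 1
  cache <- precompute_thomas(m, s, dt)
  for (i in seq_len(Tend / dt)) f <- step_diffusion_decay(f, cache)
  exact <- 2 * exp(-lambda * Tend) + exp(-mu * Tend) * cos(k * xc)
  expect_lt(max(abs(f[, 1] - exact)), 5e-3)

  # implicit scheme: stable and non-oscillatory at 100x the default dt
  f2 <- new_field(m, s, values = matrix(2 + cos(k * xc), n, 1))
  cache2 <- precompute_thomas(m, s, 1.0)
  prev <- f2[, 1]
  for (i in 1:20) {
    f2 <- step_diffusion_decay(f2, cache2)
    expect_true(all(f2[, 1] >= -1e-12))
    expect_true(all(f2[, 1] <= max(prev) + 1e-12))
    prev <- f2[, 1]
  }
})
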