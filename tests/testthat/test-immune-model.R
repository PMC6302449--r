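test_that("the heterogeneous tumor initializer draws truncated oncoprotein", {
  set.seed(123)
  tum <- init_heterogeneous_tumor(1e5)
  p <- tum$oncoprotein
  expect_true(all(p >= 0 & p <= 2))
  # truncation at +-3.33 sigma barely perturbs the moments
  expect_lt(abs(mean(p) - 1), 3 * 0.3 / sqrt(1e5) + 0.001)
  expect_lt(abs(sd(p) - 0.3), 0.003)

  # sd = 0 is degenerate
  set.seed(1)
  expect_equal(init_heterogeneous_tumor(50, sd_p = 0)$oncoprotein,
               rep(1, 50))
})

test_that("tumor packing respects the requested geometry", {
  set.seed(2)
  tum <- init_heterogeneous_tumor(200, radius = 300)
  r <- sqrt(tum$x^2 + tum$y^2)
  expect_lte(max(r) + cell_radius(2494), 300 + 1e-9)
  # cells are not stacked on top of each other
  dmin <- min(dist(cbind(tum$x, tum$y)))
  expect_gt(dmin, cell_radius(2494))
  # too tight a radius is an impossible packing
  expect_error(init_heterogeneous_tumor(200, radius = 100),
               "impossible packing")
  # 3-D packing stays inside the ball
  tum3 <- init_heterogeneous_tumor(150, radius = 150, dimensions = 3)
  expect_lte(max(sqrt(tum3$x^2 + tum3$y^2 + tum3$z^2)) + cell_radius(2494),
             150 + 1e-9)
})

test_that("motility direction blends the random and chemotactic parts", {
  # deterministic chemotaxis limit
  expect_equal(motility_direction(c(1, 0, 0), c(0, 0, 5), b = 1),
               c(0, 0, 1))
  # pure Brownian limit
  expect_equal(motility_direction(c(0, 1, 0), c(3, 3, 0), b = 0),
               c(0, 1, 0))
  # equal blend of orthogonal unit vectors
  expect_equal(motility_direction(c(1, 0, 0), c(0, 2, 0), b = 0.5),
               c(sqrt(2) / 2, sqrt(2) / 2, 0))
  # flat gradient falls back to the random direction
  expect_equal(motility_direction(c(0, 1, 0), c(0, 1e-15, 0), b = 0.9),
               c(0, 1, 0))
  # always a unit vector
  set.seed(31)
  for (i in 1:200) {
    th <- runif(1, 0, 2 * pi)
    u <- c(cos(th), sin(th), 0)
    g <- rnorm(3)
    d <- motility_direction(u, g, runif(1))
    expect_equal(sum(d^2), 1, tolerance = 1e-12)
  }
})

test_that("with b = 0 the direction distribution is uniform on the circle", {
  set.seed(77)
  th <- runif(1e4, 0, 2 * pi)
  d <- t(vapply(th, function(t)
    motility_direction(c(cos(t), sin(t)), c(1, 0), b = 0), numeric(2)))
  ang <- atan2(d[, 2], d[, 1])
  counts <- table(cut(ang, breaks = seq(-pi, pi, length.out = 13)))
  gof <- chisq.test(as.numeric(counts))
  expect_gt(gof$p.value, 0.001)
})

test_that("attachment waiting times recover 1/r_A at the study values", {
  set.seed(5)
  for (rA in c(0.033, 0.2, 1.0)) {
    tt <- simulate_attachment_times(2e4, r_A = rA, dt = 0.01)
    se <- sd(tt) / sqrt(length(tt))
    expect_lt(abs(mean(tt) - 1 / rA), 3 * se + 0.01 / 2)
  }
})

test_that("attachment lifetimes recover T_A at the study values", {
  set.seed(6)
  for (TA in c(15, 60, 120)) {
    tt <- simulate_attachment_lifetimes(2e4, T_A = TA, dt = 0.1)
    se <- sd(tt) / sqrt(length(tt))
    expect_lt(abs(mean(tt) - TA), 3 * se + 0.1)
  }
})

test_that("the kill hazard scales linearly in oncoprotein expression", {
  set.seed(8)
  t1 <- simulate_kill_times(2e4, kill_rate = 0.06, p = 1, dt = 0.01)
  t2 <- simulate_kill_times(2e4, kill_rate = 0.06, p = 2, dt = 0.01)
  se <- sqrt(sd(t1)^2 / length(t1) + 4 * sd(t2)^2 / length(t2))
  # doubling p halves the mean time to kill
  expect_lt(abs(mean(t1) - 2 * mean(t2)), 3 * se + 0.02)
})

test_that("introducing zero immune cells is the null intervention", {
  base <- immune_config(tumor_cells = 60, immune_cells = 0, duration = 180,
                        seed = 4)
  alt <- base; alt$r_A <- 1.0; alt$bias <- 0.9
  r1 <- run_cancer_immune(base)
  r2 <- run_cancer_immune(alt)
  expect_identical(final_snapshot(r1)$cells, final_snapshot(r2)$cells)
  expect_equal(sum(final_snapshot(r1)$cells$kind == "immune"), 0)
})

test_that("overwhelming kill parameters eliminate a small tumor", {
  r <- run_cancer_immune(immune_config(tumor_cells = 80, immune_cells = 60,
                                       r_A = 1.0, kill_rate = 5, bias = 0.5,
                                       T_A = 120, duration = 720, seed = 2))
  expect_lt(r$final_live_tumor, 8) # nearly every contact kills
  expect_lt(r$final_live_tumor, 80 / 4)
})

test_that("the attachment registry never dangles and targets are tumor cells", {
  r <- run_cancer_immune(immune_config(tumor_cells = 120, immune_cells = 60,
                                       kill_rate = 0.5, duration = 720,
                                       save_interval = 60, seed = 3))
  for (snap in r$snapshots) {
    cells <- snap$cells
    att <- cells$attached_to[!is.na(cells$attached_to)]
    if (length(att) > 0) {
      expect_true(all(att %in% cells$id)) # no dangling references
      tgt <- cells[match(att, cells$id), ]
      expect_true(all(tgt$kind == "tumor"))
    }
    # only immune cells hold attachments
    expect_true(all(is.na(cells$attached_to[cells$kind == "tumor"])))
  }
  # kills happened, so attachments were formed and dissolved along the way
  expect_lt(r$final_live_tumor, 120)
})
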