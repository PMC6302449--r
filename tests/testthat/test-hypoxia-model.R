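make_snapshot <- function(states) {
  n <- length(states)
  structure(list(
    time = 0,
    cells = data.frame(id = seq_len(n) - 1L, kind = rep("tumor", n),
                       x = rep(0, n), y = rep(0, n), z = rep(0, n),
                       volume = rep(2494, n),
                       radius = rep(cell_radius(2494), n), state = states,
                       oncoprotein = rep(1, n),
                       attached_to = rep(NA_integer_, n),
                       stringsAsFactors = FALSE),
    fields = NULL, mesh = NULL, substrates = NULL),
    class = "tissue_snapshot")
}

test_that("live cell fraction is the live share of cells present", {
  expect_equal(live_cell_fraction(make_snapshot(rep("live", 40))), 1)
  expect_equal(live_cell_fraction(make_snapshot(rep("necrotic", 12))), 0)
  expect_equal(live_cell_fraction(
    make_snapshot(c(rep("live", 75), rep("necrotic", 25)))), 0.75)
  # 0/0 is defined as 0
  expect_equal(live_cell_fraction(make_snapshot(character(0))), 0)
})

test_that("hypoxia configuration is validated", {
  expect_error(hypoxia_config(-1, 100), "configuration error")
  expect_error(hypoxia_config(38, 0), "configuration error")
  expect_equal(hypoxia_config(38, 100)$duration, 2880) # 48 h default
  grid <- hypoxia_study_grid()
  expect_equal(grid$oxygen, c(0, 2.5, 5, 8, 10, 15, 38, 60))
  expect_equal(grid$cells, c(1, 10, 100, 1000, 2000))
})

test_that("a short hypoxia run produces the documented outputs", {
  r <- run_hypoxia(hypoxia_config(38, 40, duration = 120, seed = 7))
  expect_s3_class(r, "hypoxia_run")
  expect_true(r$live_fraction >= 0 && r$live_fraction <= 1)
  expect_equal(names(r$result),
               c("oxygen_mmHg", "initial_cells", "seed", "final_live",
                 "final_total", "live_fraction"))
  expect_equal(r$result$live_fraction, r$live_fraction)
  # oxygen field present and bounded by the boundary condition
  f <- final_snapshot(r)$fields
  expect_true(all(f[, "oxygen"] <= 38 + 1e-9))
})

test_that("anoxia kills the whole seeding almost immediately", {
  r <- run_hypoxia(hypoxia_config(0, 30, duration = 60, seed = 1))
  expect_equal(r$live_fraction, 0)
  expect_equal(sum(final_snapshot(r)$cells$state == "necrotic"), 30)
})

test_that("well-oxygenated small seedings stay fully alive short-term", {
  r <- run_hypoxia(hypoxia_config(60, 5, duration = 360, seed = 11))
  expect_equal(r$live_fraction, 1)
})
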