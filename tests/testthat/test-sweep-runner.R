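# A fast deterministic stand-in experiment used throughout: the metric is a
# known function of the parameters plus a seeded draw.
toy_experiment <- function(params, seed, sandbox) {
  set.seed(seed)
  if (isTRUE(params$a == 666)) stop("injected failure")
  list(metric = params$a * 100 + (params$b %||% 0) + rnorm(1, sd = 1e-8))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("the parameter file enumerates the cartesian design", {
  tf <- tempfile()
  cfg <- immune_study_sweep(replicates = 1, output_root = tempfile())
  sets <- generate_parameter_file(cfg, tf)
  expect_length(sets, 27) # 3^3 combinations
  expect_length(readLines(tf), 27)

  cfg10 <- immune_study_sweep(replicates = 10, output_root = tempfile())
  sets10 <- generate_parameter_file(cfg10, tf)
  expect_length(sets10, 270)
  expect_length(readLines(tf), 270)
  # seeds are injective over (combination, replicate)
  seeds <- vapply(sets10, `[[`, numeric(1), "seed")
  expect_equal(anyDuplicated(seeds), 0)
  # first line round-trips as JSON with the declared parameter order
  first <- jsonlite::fromJSON(readLines(tf)[1])
  expect_equal(names(first$params), c("r_A", "T_A", "b"))
  expect_equal(first$params$r_A, 0.033)

  # degenerate design: one parameter, one value
  cfg1 <- sweep_config(list(a = 5), replicates = 1, base_seed = 42,
                       experiment = toy_experiment)
  s1 <- generate_parameter_file(cfg1, tf)
  expect_length(s1, 1)
  expect_equal(s1[[1]]$seed, 42)

  expect_error(sweep_config(list(a = numeric(0))), "configuration error")
})

test_that("a failing run is recorded and does not abort the sweep", {
  tf <- tempfile()
  cfg <- sweep_config(list(a = c(1, 2, 666, 4)), replicates = 1,
                      experiment = toy_experiment, workers = 2,
                      output_root = tempfile())
  generate_parameter_file(cfg, tf)
  rec <- run_sweep(tf, cfg)
  expect_equal(nrow(rec), 4)
  expect_equal(sum(rec$status == "completed"), 3)
  expect_equal(sum(rec$status == "failed"), 1)
  expect_match(rec$error[rec$status == "failed"], "injected failure")
  expect_true(all(dir.exists(rec$sandbox)))
  # the failed run carries no metric
  expect_true(is.na(rec$metric[rec$a == 666]))

  # re-running the same sweep reproduces every metric exactly
  cfg2 <- cfg; cfg2$output_root <- tempfile()
  rec2 <- run_sweep(tf, cfg2)
  expect_identical(rec$metric, rec2$metric)
})

test_that("an empty parameter file yields an empty record set", {
  tf <- tempfile(); writeLines(character(0), tf)
  cfg <- sweep_config(list(a = 1), experiment = toy_experiment,
                      output_root = tempfile())
  rec <- run_sweep(tf, cfg)
  expect_equal(nrow(rec), 0)
})

run_toy_sweep <- function(values = c(1, 2, 3), replicates = 3,
                          fail_one = FALSE) {
  tf <- tempfile()
  vals <- if (fail_one) c(values, 666) else values
  cfg <- sweep_config(list(a = vals, b = c(10, 20)), replicates = replicates,
                      experiment = toy_experiment, output_root = tempfile())
  generate_parameter_file(cfg, tf)
  run_sweep(tf, cfg)
}

test_that("aggregation reports n, mean, sample sd and failures", {
  rec <- run_toy_sweep(replicates = 3)
  agg <- aggregate_sweep(rec, "metric")
  expect_equal(nrow(agg), 6)
  row <- agg[agg$a == 2 & agg$b == 20, ]
  expect_equal(row$n, 3)
  expect_equal(row$mean, 220, tolerance = 1e-6)
  expect_equal(row$failures, 0)

  # hand-checked example: sample sd of {2, 4, 6} is 2
  fake <- rec[1:3, ]
  fake$metric <- c(2, 4, 6)
  fake$a <- 1; fake$b <- 10
  attr(fake, "param_levels") <- list(a = 1, b = 10)
  agg2 <- aggregate_sweep(fake, "metric", by = c("a", "b"))
  expect_equal(agg2$mean, 4)
  expect_equal(agg2$sd, 2)

  # identical replicates: sd 0
  fake$metric <- rep(7, 3)
  agg3 <- aggregate_sweep(fake, "metric", by = c("a", "b"))
  expect_equal(agg3$mean, 7)
  expect_equal(agg3$sd, 0)

  # aggregation is permutation-invariant over record order
  rec_shuffled <- rec[sample(nrow(rec)), ]
  attributes(rec_shuffled)$param_levels <- attr(rec, "param_levels")
  agg4 <- aggregate_sweep(rec_shuffled, "metric")
  expect_equal(agg4$mean[order(agg4$a, agg4$b)],
               agg$mean[order(agg$a, agg$b)])
})

test_that("failed runs are excluded from statistics but counted", {
  rec <- run_toy_sweep(replicates = 2, fail_one = TRUE)
  agg <- aggregate_sweep(rec, "metric")
  bad <- agg[agg$a == 666 & agg$b == 10, ]
  expect_equal(bad$n, 0)
  expect_true(is.na(bad$mean))
  expect_equal(bad$failures, 2)

  all_failed <- rec[rec$status == "failed", ]
  attr(all_failed, "param_levels") <- attr(rec, "param_levels")
  expect_error(aggregate_sweep(all_failed, "metric"), "empty-result")
})

test_that("heatmap grids follow declared value order and mark empty cells", {
  rec <- run_toy_sweep(replicates = 2, fail_one = TRUE)
  agg <- aggregate_sweep(rec, "metric")
  g <- heatmap_table(agg, x_param = "a", y_param = "b")
  expect_equal(dim(g), c(2, 4))
  expect_equal(colnames(g), c("1", "2", "3", "666"))
  expect_equal(g["10", "2"], agg$mean[agg$a == 2 & agg$b == 10])
  # all-failed combination is empty, not zero
  expect_true(all(is.na(g[, "666"])))
  expect_equal(attr(g, "n")["10", "666"], 0L)
  # transposing the axes transposes the grid
  gt <- heatmap_table(agg, x_param = "b", y_param = "a")
  expect_equal(unclass(g)[, ], t(unclass(gt))[, ], ignore_attr = TRUE)

  # a third swept parameter must be pinned
  rec3 <- run_toy_sweep(replicates = 1)
  agg3 <- aggregate_sweep(rec3, "metric")
  agg3$c <- 1
  attr(agg3, "param_levels") <- c(attr(agg3, "param_levels"), list(c = 1))
  expect_error(heatmap_table(agg3, "a", "b"), "ambiguity error")
  expect_silent(heatmap_table(agg3, "a", "b", fixed = list(c = 1)))
})
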