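#' Configure a parameter sweep
#'
#' A local model-exploration harness: the cartesian product of the declared
#' parameter value lists, expanded by replicates with derived seeds, is
#' written to a parameter file (one parameter set per line) and executed in
#' per-run sandbox directories, failure-tolerantly and optionally
#' process-parallel. Seeds derive from
#' `base_seed + combination_index * replicates + replicate_index`, so the
#' seed schedule is injective over (combination, replicate) and results are
#' independent of scheduling order.
#'
#' @param parameters Named list of value vectors, in declared order (the
#'   first parameter is the most significant in the combination order).
#' @param replicates Replicates per combination (>= 1).
#' @param base_seed Integer base seed.
#' @param experiment `"hypoxia"`, `"immune"`, or a function
#'   `function(params, seed, sandbox)` returning a named list of numeric
#'   metrics (the pluggable objective-metric hook).
#' @param workers Process-parallel worker count.
#' @param output_root Directory that will hold the per-run sandboxes.
#' @param defaults Named list of fixed arguments merged into each run's
#'   parameters (e.g. a shortened duration).
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(parameters, replicates = 1, base_seed = 1,
                         experiment = "hypoxia", workers = 1,
                         output_root = tempfile("sweep"),
                         defaults = list()) {
  if (length(parameters) == 0 || is.null(names(parameters)) ||
      any(names(parameters) == ""))
    stop("configuration error: parameters must be a named list")
  if (any(vapply(parameters, length, 1L) == 0))
    stop("configuration error: every parameter needs at least one value")
  if (replicates < 1) stop("configuration error: replicates must be >= 1")
  structure(list(parameters = parameters, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), experiment = experiment,
                 workers = as.integer(workers), output_root = output_root,
                 defaults = defaults),
            class = "sweep_config")
}

#' The cancer-immune study sweep design
#'
#' Attachment rate \{0.033, 0.2, 1.0\}/min x attachment lifetime
#' \{15, 60, 120\} min x migration bias \{0.25, 0.5, 0.75\}, 10 replicates:
#' 27 combinations, 270 parameter sets.
#'
#' @param replicates Replicates per combination (default 10).
#' @param ... Passed to [sweep_config()].
#' @return A `sweep_config`.
#' @export
immune_study_sweep <- function(replicates = 10, ...) {
  sweep_config(parameters = list(r_A = c(0.033, 0.2, 1.0),
                                 T_A = c(15, 60, 120),
                                 b = c(0.25, 0.5, 0.75)),
               replicates = replicates, experiment = "immune", ...)
}

combo_values <- function(parameters, ci) {
  # ci is 0-based; the first declared parameter is the most significant
  lens <- vapply(parameters, length, 1L)
  out <- vector("list", length(lens))
  rem <- ci
  for (d in rev(seq_along(lens))) {
    out[[d]] <- parameters[[d]][rem %% lens[d] + 1]
    rem <- rem %/% lens[d]
  }
  names(out) <- names(parameters)
  out
}

#' Generate the sweep parameter file
#'
#' Writes one parameter set per line (JSON-lines dialect): the cartesian
#' product of the declared value lists in lexicographic order over the
#' declared parameter order, each combination expanded by replicates with
#' its derived seed.
#'
#' @param config A [sweep_config()].
#' @param path Output file path.
#' @return (Invisibly) the list of parameter sets, each with `run_id`,
#'   `combination`, `replicate`, `seed`, and `params`.
#' @export
generate_parameter_file <- function(config, path) {
  stopifnot(inherits(config, "sweep_config"))
  lens <- vapply(config$parameters, length, 1L)
  n_combo <- prod(lens)
  sets <- vector("list", n_combo * config$replicates)
  line <- 0L
  for (ci in seq_len(n_combo) - 1L) {
    vals <- combo_values(config$parameters, ci)
    for (ri in seq_len(config$replicates) - 1L) {
      line <- line + 1L
      sets[[line]] <- list(
        run_id = sprintf("run_%05d", line),
        combination = ci, replicate = ri,
        seed = config$base_seed + ci * config$replicates + ri,
        params = vals)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sets)
    writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA), con)
  invisible(sets)
}

default_experiments <- list(
  hypoxia = function(params, seed, sandbox) {
    args <- params
    args$seed <- seed
    run <- do.call(hypoxia_config,
                   args[names(args) %in% names(formals(hypoxia_config))])
    out <- run_hypoxia(run)
    utils::write.csv(out$result, file.path(sandbox, "result.csv"),
                     row.names = FALSE)
    list(live_fraction = out$live_fraction,
         live_tumor_count = out$final_live,
         final_total = out$final_total)
  },
  immune = function(params, seed, sandbox) {
    args <- params
    if (!is.null(args$b)) { args$bias <- args$b; args$b <- NULL }
    args$seed <- seed
    run <- do.call(immune_config,
                   args[names(args) %in% names(formals(immune_config))])
    out <- run_cancer_immune(run)
    utils::write.csv(out$live_tumor, file.path(sandbox, "live_tumor.csv"),
                     row.names = FALSE)
    list(live_tumor_count = out$final_live_tumor)
  })

#' Execute a sweep from its parameter file
#'
#' Each parameter set runs in its own sandbox subdirectory with its own log.
#' A failing run is recorded as `failed` (with the error message) and does
#' not abort the sweep. Runs execute process-parallel up to `workers`; the
#' per-run seeds make the results independent of scheduling order.
#'
#' @param parameter_file Path written by [generate_parameter_file()].
#' @param config The [sweep_config()].
#' @return A data frame of run records (class `sweep_records`): one row per
#'   run with the parameters, `seed`, `status`, `sandbox`, `error`, elapsed
#'   wall seconds, and one column per extracted metric.
#' @export
run_sweep <- function(parameter_file, config) {
  stopifnot(inherits(config, "sweep_config"))
  if (!file.exists(parameter_file))
    stop("I/O error: parameter file does not exist")
  root <- config$output_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root) || file.access(root, 2) != 0)
    stop("I/O error: output root is not writable")
  lines <- readLines(parameter_file)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, jsonlite::fromJSON)
  fn <- config$experiment
  if (is.character(fn)) {
    fn <- default_experiments[[fn]]
    if (is.null(fn)) stop("configuration error: unknown experiment")
  }
  one <- function(s) {
    sandbox <- file.path(root, s$run_id)
    dir.create(sandbox, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(sandbox, "run.log")
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch({
      params <- utils::modifyList(as.list(config$defaults),
                                  as.list(s$params))
      metrics <- fn(params, s$seed, sandbox)
      if (!is.list(metrics) || is.null(names(metrics)))
        stop("experiment must return a named list of metrics")
      cat(sprintf("%s completed (seed %d)\n", s$run_id, s$seed), file = log)
      list(status = "completed", error = NA_character_, metrics = metrics)
    }, error = function(e) {
      cat(sprintf("%s failed: %s\n", s$run_id, conditionMessage(e)),
          file = log)
      list(status = "failed", error = conditionMessage(e), metrics = list())
    })
    rec$wall_s <- proc.time()[["elapsed"]] - t0
    rec$run_id <- s$run_id
    rec$combination <- s$combination
    rec$replicate <- s$replicate
    rec$seed <- s$seed
    rec$params <- s$params
    rec$sandbox <- sandbox
    rec
  }
  recs <- if (config$workers > 1) {
    parallel::mclapply(sets, one, mc.cores = config$workers)
  } else {
    lapply(sets, one)
  }
  # mclapply can surface worker-level failures as error objects: record them
  recs <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (inherits(r, "try-error") || !is.list(r) || is.null(r$status)) {
      s <- sets[[i]]
      list(status = "failed", error = "worker error", metrics = list(),
           wall_s = NA_real_, run_id = s$run_id, combination = s$combination,
           replicate = s$replicate, seed = s$seed, params = s$params,
           sandbox = file.path(root, s$run_id))
    } else r
  })
  metric_names <- unique(unlist(lapply(recs, function(r) names(r$metrics))))
  pnames <- names(config$parameters)
  rows <- lapply(recs, function(r) {
    row <- c(list(run_id = r$run_id, combination = r$combination,
                  replicate = r$replicate, seed = r$seed),
             lapply(stats::setNames(pnames, pnames),
                    function(p) r$params[[p]]),
             list(status = r$status, error = r$error, sandbox = r$sandbox,
                  wall_s = r$wall_s),
             lapply(stats::setNames(metric_names, metric_names), function(mn) {
               v <- r$metrics[[mn]]
               if (is.null(v)) NA_real_ else as.numeric(v)
             }))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(run_id = character(0), status = character(0))
  structure(out, param_levels = config$parameters, metric_names = metric_names,
            class = c("sweep_records", "data.frame"))
}

#' Aggregate sweep metrics per parameter combination
#'
#' For every parameter combination: replicate count `n` (completed runs
#' only), the sample mean and sample standard deviation of the metric over
#' completed runs, and the number of failed runs (excluded from the
#' statistics, counted separately).
#'
#' @param records A [run_sweep()] data frame.
#' @param metric Metric column name.
#' @param by Character vector of parameter names to group by (defaults to
#'   all swept parameters).
#' @return A data frame (class `sweep_summary`): the grouping columns, then
#'   `n`, `mean`, `sd`, `failures`.
#' @export
aggregate_sweep <- function(records, metric, by = NULL) {
  levels_ <- attr(records, "param_levels")
  if (is.null(by)) by <- names(levels_)
  if (!all(by %in% names(records)))
    stop("configuration error: unknown grouping parameter")
  if (!metric %in% names(records))
    stop("configuration error: unknown metric '", metric, "'")
  if (!any(records$status == "completed"))
    stop("empty-result error: no completed runs to aggregate")
  keyf <- lapply(by, function(p) {
    lv <- levels_[[p]]
    if (is.null(lv)) factor(records[[p]])
    else factor(records[[p]], levels = lv)
  })
  names(keyf) <- by
  key <- interaction(rev(keyf), drop = TRUE, lex.order = FALSE)
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(ix) {
    sub <- records[ix, , drop = FALSE]
    ok <- sub$status == "completed"
    vals <- sub[[metric]][ok]
    out <- sub[1, by, drop = FALSE]
    out$n <- sum(ok)
    out$mean <- if (any(ok)) mean(vals) else NA_real_
    out$sd <- if (sum(ok) >= 2) stats::sd(vals) else if (sum(ok) == 1) 0 else NA_real_
    out$failures <- sum(!ok)
    out
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, param_levels = levels_, metric = metric,
            class = c("sweep_summary", "data.frame"))
}

#' Pivot a sweep summary into a heatmap grid
#'
#' Builds the 2-D grid of means (rows = `y_param` values, columns =
#' `x_param` values, both in declared value order) with the completed
#' replicate count per cell kept in attribute `"n"`. Any remaining swept
#' parameter must be pinned through `fixed`; a combination with no completed
#' runs is marked empty (`NA`), not zero.
#'
#' @param summary A [aggregate_sweep()] result.
#' @param x_param,y_param Parameter names for the grid axes.
#' @param fixed Named list pinning every other swept parameter.
#' @return A numeric matrix of class `sweep_heatmap` with attribute `n`.
#' @export
heatmap_table <- function(summary, x_param, y_param, fixed = list()) {
  levels_ <- attr(summary, "param_levels")
  pcols <- intersect(names(levels_), names(summary))
  if (length(pcols) == 0)
    pcols <- setdiff(names(summary), c("n", "mean", "sd", "failures"))
  others <- setdiff(pcols, c(x_param, y_param))
  un <- setdiff(others, names(fixed))
  if (length(un) > 0)
    stop("ambiguity error: unpinned parameter(s): ", paste(un, collapse = ", "))
  sub <- summary
  for (p in names(fixed))
    if (p %in% names(sub)) sub <- sub[sub[[p]] == fixed[[p]], , drop = FALSE]
  xv <- if (!is.null(levels_[[x_param]])) levels_[[x_param]] else
    sort(unique(sub[[x_param]]))
  yv <- if (!is.null(levels_[[y_param]])) levels_[[y_param]] else
    sort(unique(sub[[y_param]]))
  g <- matrix(NA_real_, nrow = length(yv), ncol = length(xv),
              dimnames = list(as.character(yv), as.character(xv)))
  nm <- matrix(0L, nrow = length(yv), ncol = length(xv),
               dimnames = dimnames(g))
  for (r in seq_len(nrow(sub))) {
    i <- match(as.character(sub[[y_param]][r]), rownames(g))
    j <- match(as.character(sub[[x_param]][r]), colnames(g))
    if (!is.na(i) && !is.na(j) && sub$n[r] > 0) {
      g[i, j] <- sub$mean[r]
      nm[i, j] <- sub$n[r]
    }
  }
  structure(g, n = nm, x_param = x_param, y_param = y_param,
            class = c("sweep_heatmap", "matrix", "array"))
}
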