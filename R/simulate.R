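#' Assemble a simulation configuration
#'
#' Bundles the mesh, substrate system, initial cells, phenotype and
#' mechanics parameters, optional immune module, and the multi-rate time
#' stepping into one validated configuration. The three rates default to
#' biotransport `dt = 0.01` min, mechanics `dt = 0.1` min, and cell
#' processes `dt = 6` min.
#'
#' @param mesh A [create_mesh()] object.
#' @param substrates A [substrate_system()]; may be omitted (`NULL`) for
#'   purely mechanical simulations.
#' @param cells Data frame of initial cells with columns `kind` ("tumor" or
#'   "immune"), `x`, `y`, `z`, `volume`, `oncoprotein` (see
#'   [init_heterogeneous_tumor()]).
#' @param tumor A [tumor_phenotype()].
#' @param mechanics A [mechanics_params()].
#' @param immune An [immune_params()] or `NULL` for no immune module.
#' @param duration Simulated time, min.
#' @param dt_diffusion,dt_mechanics,dt_phenotype The three time steps, min.
#' @param save_interval Snapshot cadence, min; `NULL` saves only the initial
#'   and final states.
#' @param oxygen,chemokine Substrate names bound to the oxygen and
#'   immunostimulatory-factor roles (`NULL` when absent).
#' @param seed Integer seed for the run's single random generator.
#' @return A list of class `tissue_config`.
#' @export
tissue_config <- function(mesh, substrates = NULL, cells,
                          tumor = tumor_phenotype(),
                          mechanics = mechanics_params(),
                          immune = NULL,
                          duration,
                          dt_diffusion = 0.01, dt_mechanics = 0.1,
                          dt_phenotype = 6,
                          save_interval = NULL,
                          oxygen = "oxygen", chemokine = NULL,
                          seed = 1L) {
  stopifnot(inherits(mesh, "cartesian_mesh"))
  if (is.null(substrates))
    substrates <- substrate_system("none", D = 0, lambda = 0)
  if (!is.numeric(duration) || duration < 0)
    stop("configuration error: duration must be >= 0")
  if (dt_diffusion <= 0 || dt_mechanics <= 0 || dt_phenotype <= 0)
    stop("configuration error: time steps must be > 0")
  if (dt_mechanics < dt_diffusion || dt_phenotype < dt_mechanics)
    stop("configuration error: expect dt_diffusion <= dt_mechanics <= dt_phenotype")
  need <- c("kind", "x", "y", "z", "volume", "oncoprotein")
  if (nrow(cells) > 0 && !all(need %in% names(cells)))
    stop("configuration error: cells need columns ",
         paste(need, collapse = ", "))
  if (nrow(cells) > 0 && !all(cells$kind %in% c("tumor", "immune")))
    stop("configuration error: cell kind must be 'tumor' or 'immune'")
  find_sub <- function(nm) {
    if (is.null(nm)) return(-1L)
    i <- match(nm, substrates$names)
    if (is.na(i)) stop("configuration error: no substrate named '", nm, "'")
    i - 1L
  }
  cfg <- list(mesh = mesh, substrates = substrates, cells = cells,
              tumor = tumor, mechanics = mechanics,
              immune = if (is.null(immune)) immune_params(n = 0) else immune,
              duration = duration, dt_diffusion = dt_diffusion,
              dt_mechanics = dt_mechanics, dt_phenotype = dt_phenotype,
              save_interval = if (is.null(save_interval)) -1 else save_interval,
              oxygen_index = find_sub(oxygen),
              chemokine_index = find_sub(chemokine),
              seed = as.integer(seed))
  class(cfg) <- "tissue_config"
  cfg
}

kind_code <- function(kind) ifelse(kind == "immune", 1L, 0L)
state_names <- c("live", "apoptotic", "necrotic")

config_to_cpp <- function(cfg) {
  cells <- cfg$cells
  list(
    mesh = mesh_to_list(cfg$mesh),
    substrates = substrates_to_list(cfg$substrates),
    oxygen = cfg$oxygen_index, chemokine = cfg$chemokine_index,
    cells = list(kind = kind_code(cells$kind),
                 x = as.numeric(cells$x), y = as.numeric(cells$y),
                 z = as.numeric(cells$z),
                 volume = as.numeric(cells$volume),
                 oncoprotein = as.numeric(cells$oncoprotein)),
    tumor = unclass(cfg$tumor),
    mechanics = list(repulsion = cfg$mechanics$repulsion,
                     adhesion = cfg$mechanics$adhesion,
                     max_adhesion_factor = cfg$mechanics$max_adhesion_factor,
                     attach_adhesion_mult = cfg$mechanics$attach_adhesion_mult),
    immune = unclass(cfg$immune),
    times = list(duration = cfg$duration, dt_diffusion = cfg$dt_diffusion,
                 dt_mechanics = cfg$dt_mechanics,
                 dt_phenotype = cfg$dt_phenotype,
                 save_interval = cfg$save_interval),
    seed = cfg$seed)
}

wrap_snapshot <- function(s, cfg) {
  att <- s$attached_to
  att[att < 0] <- NA_integer_
  cells <- data.frame(
    id = s$id,
    kind = c("tumor", "immune")[s$kind + 1L],
    x = s$x, y = s$y, z = s$z,
    volume = s$volume, radius = s$radius,
    state = state_names[s$state + 1L],
    oncoprotein = s$oncoprotein,
    attached_to = att,
    stringsAsFactors = FALSE)
  fields <- s$fields
  colnames(fields) <- cfg$substrates$names
  structure(list(time = s$time, cells = cells, fields = fields,
                 mesh = cfg$mesh, substrates = cfg$substrates),
            class = "tissue_snapshot")
}

#' @export
print.tissue_snapshot <- function(x, ...) {
  tab <- table(factor(x$cells$state, levels = state_names))
  cat(sprintf("Snapshot at t = %g min: %d cells (%s)\n", x$time,
              nrow(x$cells),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Run a tissue simulation
#'
#' Executes the full multi-rate loop. Each mechanics step performs, in
#' order: (1) biotransport sub-steps (bulk sources, cell-centered
#' secretion/uptake, implicit LOD diffusion-decay); (2) when a phenotype
#' step is due, phenotype advancement for every cell (death evaluated before
#' division, deterministic necrosis below the oxygen threshold, dead-cell
#' shrinkage) with cached division/removal lists; (3) serial processing of
#' those lists, dissolving any attachments to removed cells first; immune
#' attach/kill/detach and motility-direction updates; (4) velocity
#' evaluation on the interaction grid; (5) Adams-Bashforth position update;
#' (6) time advance. All stochastic draws consume one seeded generator in a
#' fixed order, so identical configurations are bit-identical.
#'
#' @param config A [tissue_config()].
#' @return An object of class `tissue_sim`: a list with `snapshots` (list of
#'   `tissue_snapshot`), `timeseries` (data frame of counts per phenotype
#'   step), `counters`, and the `config`.
#' @export
simulate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_config"))
  raw <- cpp_run_simulation(config_to_cpp(config))
  snaps <- lapply(raw$snapshots, wrap_snapshot, cfg = config)
  ts <- as.data.frame(raw$timeseries)
  structure(list(snapshots = snaps, timeseries = ts,
                 counters = raw$counters, config = config),
            class = "tissue_sim")
}

#' @export
print.tissue_sim <- function(x, ...) {
  fin <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf("Tissue simulation: %g min, %d snapshots\n",
              x$config$duration, length(x$snapshots)))
  cat(sprintf("  cells: %d initial, %g divisions, %g removed, %d final\n",
              x$counters$initial, x$counters$divisions, x$counters$removed,
              nrow(fin$cells)))
  invisible(x)
}

#' @export
summary.tissue_sim <- function(object, ...) {
  ts <- object$timeseries
  cat("Population over time (per phenotype step):\n")
  print(utils::tail(ts, 5))
  invisible(ts)
}

#' @export
plot.tissue_sim <- function(x, ...) {
  ts <- x$timeseries
  graphics::matplot(ts$time / 60, cbind(ts$live_tumor, ts$apoptotic,
                                        ts$necrotic, ts$immune),
                    type = "l", lty = 1, lwd = 2,
                    col = c("forestgreen", "cyan3", "tan4", "red"),
                    xlab = "time (h)", ylab = "cells", ...)
  graphics::legend("topleft",
                   legend = c("live tumor", "apoptotic", "necrotic", "immune"),
                   col = c("forestgreen", "cyan3", "tan4", "red"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Final snapshot of a simulation
#' @param sim A `tissue_sim` object.
#' @return The last `tissue_snapshot`.
#' @export
final_snapshot <- function(sim) sim$snapshots[[length(sim$snapshots)]]
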