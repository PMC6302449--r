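#' Configure the 2-D hypoxia experiment
#'
#' Oxygen-limited tumor growth over 48 simulated hours: cells are seeded in
#' a central disc, oxygen is held at `boundary_oxygen` on the domain
#' boundary (Dirichlet) and consumed by live cells, and the outcome metric
#' is the live cell fraction at the end of the run. The study grid explores
#' boundary oxygenation from anoxia (0 mmHg) to well-oxygenated breast
#' tissue (60 mmHg) against initial populations from 1 to 2000 cells.
#'
#' @param boundary_oxygen Boundary oxygen tension, mmHg (0 to 60 covers the
#'   study range).
#' @param initial_cells Seeded cell count (>= 1).
#' @param duration Simulated time, min (default 2880 = 48 h).
#' @param domain_edge Square domain edge, um. The default leaves room for a
#'   2000-cell tumor to roughly double without touching the boundary.
#' @param save_interval Snapshot cadence, min (`NULL`: initial and final
#'   only).
#' @param seed Integer seed.
#' @return A list of class `hypoxia_config`.
#' @export
hypoxia_config <- function(boundary_oxygen, initial_cells,
                           duration = 2880, domain_edge = 1200,
                           save_interval = NULL, seed = 1L) {
  if (boundary_oxygen < 0)
    stop("configuration error: boundary_oxygen must be >= 0")
  if (initial_cells < 1)
    stop("configuration error: initial_cells must be >= 1")
  structure(as.list(environment()), class = "hypoxia_config")
}

#' The printed study grids of the hypoxia experiment
#'
#' Boundary oxygenation values \{0, 2.5, 5, 8, 10, 15, 38, 60\} mmHg and
#' initial cell counts \{1, 10, 100, 1000, 2000\}.
#' @return A list with elements `oxygen` and `cells`.
#' @export
hypoxia_study_grid <- function() {
  list(oxygen = c(0, 2.5, 5, 8, 10, 15, 38, 60),
       cells = c(1, 10, 100, 1000, 2000))
}

#' Run the 2-D hypoxia experiment
#'
#' @param config A [hypoxia_config()].
#' @return An object of class `hypoxia_run`: the underlying `tissue_sim`
#'   plus `live_fraction`, `final_live`, `final_total`, and a one-row
#'   `result` data frame (columns `oxygen_mmHg, initial_cells, seed,
#'   final_live, final_total, live_fraction`).
#' @examples
#' \donttest{
#' run <- run_hypoxia(hypoxia_config(60, 25, duration = 360, seed = 3))
#' run$live_fraction
#' }
#' @export
run_hypoxia <- function(config) {
  stopifnot(inherits(config, "hypoxia_config"))
  edge <- config$domain_edge
  nside <- max(3L, as.integer(round(edge / 20)))
  mesh <- create_mesh(nside, nside, 1L,
                      origin = c(-edge / 2, -edge / 2, -10))
  subs <- substrate_system("oxygen", D = 1e5, lambda = 0.1,
                           boundary = "dirichlet",
                           boundary_value = config$boundary_oxygen)
  set.seed(config$seed)
  cells <- init_heterogeneous_tumor(config$initial_cells, mean_p = 1,
                                    sd_p = 0, dimensions = 2)
  cfg <- tissue_config(mesh, subs, cells,
                       duration = config$duration,
                       save_interval = config$save_interval,
                       oxygen = "oxygen",
                       seed = config$seed)
  sim <- simulate_tissue(cfg)
  fin <- final_snapshot(sim)
  lf <- live_cell_fraction(fin)
  res <- data.frame(oxygen_mmHg = config$boundary_oxygen,
                    initial_cells = config$initial_cells,
                    seed = config$seed,
                    final_live = sum(fin$cells$state == "live"),
                    final_total = nrow(fin$cells),
                    live_fraction = lf)
  structure(c(sim, list(live_fraction = lf,
                        final_live = res$final_live,
                        final_total = res$final_total,
                        result = res, study = config)),
            class = c("hypoxia_run", "tissue_sim"))
}

#' @export
print.hypoxia_run <- function(x, ...) {
  s <- x$study
  cat(sprintf(
    "Hypoxia run: %g mmHg boundary oxygen, %d initial cells, %g h\n",
    s$boundary_oxygen, s$initial_cells, s$duration / 60))
  cat(sprintf("  final: %d live / %d present, live fraction %.3f\n",
              x$final_live, x$final_total, x$live_fraction))
  invisible(x)
}

#' Live cell fraction of a snapshot
#'
#' Live cells divided by all cells present (live + apoptotic + necrotic);
#' an empty snapshot is defined as 0.
#'
#' @param snapshot A `tissue_snapshot` (immune cells, if any, are excluded).
#' @return Fraction in \[0, 1\].
#' @examples
#' # 75 live + 25 necrotic -> 0.75
#' @export
live_cell_fraction <- function(snapshot) {
  cells <- snapshot$cells
  cells <- cells[cells$kind == "tumor", , drop = FALSE]
  if (nrow(cells) == 0) return(0)
  sum(cells$state == "live") / nrow(cells)
}
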