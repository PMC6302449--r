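#' Immune cell parameters
#'
#' Parameters of the adaptive immune response model. An unattached immune
#' cell in physical contact with a live tumor cell attaches with per-step
#' probability `r_A * dt`; an attached cell attempts to kill its target with
#' probability `r_i * p_j * dt` (scaling with the target's oncoprotein
#' expression `p_j`) and otherwise detaches with probability `dt / T_A`.
#' Unattached cells migrate by a biased random walk along the
#' immunostimulatory-factor gradient (see [motility_direction()]); attached
#' cells do not migrate and are tethered to their target by a boosted
#' adhesion.
#'
#' Defaults: `r_A = 0.2`/min (mean time to attachment 5 min in sustained
#' contact), `T_A = 60` min, `bias = 0.5`; study grids commonly explore
#' `r_A` in \{0.033, 0.2, 1.0\}/min, `T_A` in \{15, 60, 120\} min and `bias`
#' in \{0.25, 0.5, 0.75\}.
#'
#' @param n Number of immune cells to introduce (0 disables the module).
#' @param introduction_time Time at which immune cells appear, min.
#' @param r_A Attachment rate, 1/min.
#' @param T_A Mean attachment lifetime, min (> 0).
#' @param bias Migration bias in \[0, 1\]: 0 is pure Brownian motion, 1 is
#'   deterministic chemotaxis.
#' @param kill_rate Kill rate at `p = 1`, 1/min.
#' @param speed Migration speed, um/min.
#' @param persistence_time Mean time between motility-direction updates,
#'   min.
#' @param placement_factor Introduction shell radius as a multiple of the
#'   tumor bounding radius.
#' @param volume Immune cell volume, um^3.
#' @param gradient_epsilon Gradient norm below which the chemokine field is
#'   treated as flat and motility is purely random.
#' @return A list of class `immune_params`.
#' @export
immune_params <- function(n = 0, introduction_time = 0, r_A = 0.2, T_A = 60,
                          bias = 0.5, kill_rate = 0.06, speed = 1,
                          persistence_time = 10, placement_factor = 1.1,
                          volume = 905, gradient_epsilon = 1e-12) {
  if (r_A < 0 || kill_rate < 0) stop("configuration error: rates must be >= 0")
  if (T_A <= 0) stop("configuration error: T_A must be > 0")
  if (bias < 0 || bias > 1) stop("configuration error: bias must be in [0, 1]")
  structure(list(n = as.integer(n), introduction_time = introduction_time,
                 r_A = r_A, T_A = T_A, bias = bias, kill_rate = kill_rate,
                 speed = speed, persistence_time = persistence_time,
                 placement_factor = placement_factor, volume = volume,
                 gradient_epsilon = gradient_epsilon),
            class = "immune_params")
}

# truncated-normal oncoprotein draws: rejection (redraw), not clipping, so
# no probability mass accumulates at the bounds
draw_oncoprotein <- function(n, mean_p, sd_p, lower = 0, upper = 2) {
  if (sd_p == 0) return(rep(mean_p, n))
  out <- rnorm(n, mean_p, sd_p)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean_p, sd_p)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Initialize a heterogeneous immunogenic tumor
#'
#' Packs `n` tumor cells into a disc (2-D) or ball (3-D) around `center`
#' on a compact hexagonal (2-D) or stacked-layer (3-D) lattice, and assigns
#' each cell an oncoprotein expression drawn from Normal(`mean_p`, `sd_p`)
#' truncated to \[0, 2\] by rejection sampling. `p` scales both the cell's
#' proliferation and its immunogenicity.
#'
#' Uses R's global random number generator; call `set.seed()` first for
#' reproducibility.
#'
#' @param n Number of tumor cells (>= 1).
#' @param radius Optional target tumor radius, um. When given, the lattice
#'   is scaled to fit `n` cells inside; a spacing below 1.8 cell radii is
#'   rejected as an impossible packing. When `NULL` the radius follows from
#'   confluent spacing.
#' @param mean_p,sd_p Oncoprotein mean and standard deviation (defaults 1
#'   and 0.3).
#' @param cell_volume Cell volume, um^3.
#' @param dimensions 2 or 3.
#' @param center Center of the tumor (length 3).
#' @return Data frame with columns `kind`, `x`, `y`, `z`, `volume`,
#'   `oncoprotein` suitable for [tissue_config()].
#' @examples
#' set.seed(1)
#' tum <- init_heterogeneous_tumor(100)
#' range(tum$oncoprotein)  # within [0, 2]
#' @export
init_heterogeneous_tumor <- function(n, radius = NULL, mean_p = 1,
                                     sd_p = 0.3, cell_volume = 2494,
                                     dimensions = 2, center = c(0, 0, 0)) {
  if (n < 1) stop("configuration error: n must be >= 1")
  r_cell <- cell_radius(cell_volume)
  spacing <- 2 * r_cell * 0.95 # slight compression: confluent packing
  if (dimensions == 2) {
    # hexagonal lattice, sites sorted by distance from center
    nring <- ceiling(sqrt(n / pi) * 2) + 2
    ii <- seq(-nring, nring)
    sites <- expand.grid(i = ii, j = ii)
    sx <- (sites$i + 0.5 * (sites$j %% 2)) * spacing
    sy <- sites$j * spacing * sqrt(3) / 2
    sz <- rep(0, length(sx))
  } else {
    nring <- ceiling((n * 3 / (4 * pi))^(1 / 3)) + 2
    ii <- seq(-nring, nring)
    sites <- expand.grid(i = ii, j = ii, k = ii)
    sx <- (sites$i + 0.5 * ((sites$j + sites$k) %% 2)) * spacing
    sy <- (sites$j + 1 / 3 * (sites$k %% 2)) * spacing * sqrt(3) / 2
    sz <- sites$k * spacing * sqrt(2 / 3)
  }
  d2 <- sx^2 + sy^2 + sz^2
  if (length(d2) < n) stop("internal error: lattice too small")
  ord <- order(d2)[seq_len(n)]
  sx <- sx[ord]; sy <- sy[ord]; sz <- sz[ord]
  if (!is.null(radius)) {
    fit <- sqrt(max(sx^2 + sy^2 + sz^2)) + r_cell
    scale <- radius / fit
    if (scale * spacing < 1.8 * r_cell)
      stop("configuration error: impossible packing density for this radius")
    sx <- sx * scale; sy <- sy * scale; sz <- sz * scale
  }
  data.frame(kind = "tumor",
             x = center[1] + sx, y = center[2] + sy, z = center[3] + sz,
             volume = cell_volume,
             oncoprotein = draw_oncoprotein(n, mean_p, sd_p),
             stringsAsFactors = FALSE)
}

#' Biased random-walk motility direction
#'
#' Blends a random unit vector `u` with the normalized chemokine gradient:
#' \deqn{d = \frac{(1-b)u + b\,\nabla c / \|\nabla c\|}
#'               {\|(1-b)u + b\,\nabla c / \|\nabla c\|\|}.}
#' `b = 0` gives pure Brownian motion (`d = u`), `b = 1` deterministic
#' chemotaxis along the gradient. A gradient with norm below `eps` is
#' treated as flat and returns `u` unchanged -- immune cells in the flat
#' chemokine plateau at a tumor's center revert to an unbiased walk. If the
#' blended vector is degenerate (norm below `eps`, possible when `u` opposes
#' the gradient at `b = 0.5`), a fresh `u` is drawn.
#'
#' Uses R's global random number generator for redraws.
#'
#' @param u Unit vector (the random component).
#' @param grad_c Chemokine gradient vector.
#' @param b Migration bias in \[0, 1\].
#' @param eps Flat-gradient threshold (field units per um).
#' @return Unit direction vector.
#' @export
motility_direction <- function(u, grad_c, b, eps = 1e-12) {
  if (b < 0 || b > 1) stop("bias must be in [0, 1]")
  gn <- sqrt(sum(grad_c^2))
  if (gn < eps) return(u / sqrt(sum(u^2)))
  ghat <- grad_c / gn
  for (i in 1:100) {
    v <- (1 - b) * u + b * ghat
    vn <- sqrt(sum(v^2))
    if (vn >= eps) return(v / vn)
    # degenerate blend: redraw the random component
    th <- stats::runif(1, 0, 2 * pi)
    u <- if (length(u) == 2) c(cos(th), sin(th)) else {
      z <- stats::runif(1, -1, 1); s <- sqrt(1 - z^2)
      c(s * cos(th), s * sin(th), z)
    }
  }
  stop("failed to draw a non-degenerate direction")
}

#' Simulate attachment waiting times
#'
#' The attachment hazard is a per-step Bernoulli process: an immune cell in
#' continuous contact attaches in each step with probability
#' `min(1, r_A * dt)`. Waiting times are therefore geometric in steps; this
#' draws the first-success step count for `n` independent trials and
#' converts to minutes. The mean waiting time approaches `1 / r_A` (5 min at
#' the default rate).
#'
#' Uses R's global random number generator.
#'
#' @param n Number of trials.
#' @param r_A Attachment rate, 1/min.
#' @param dt Step size, min.
#' @return Numeric vector of waiting times, min.
#' @export
simulate_attachment_times <- function(n, r_A = 0.2, dt = 0.01) {
  p <- min(1, r_A * dt)
  (rgeom(n, p) + 1) * dt
}

#' Simulate attachment lifetimes
#'
#' An attached immune cell that never kills detaches in each step with
#' probability `min(1, dt / T_A)`; the mean lifetime is `T_A`. With a
#' nonzero `kill_rate` the kill attempt (probability
#' `min(1, kill_rate * p * dt)`, evaluated before detachment as in the
#' engine) competes with detachment, and the returned times are
#' time-to-first-event with the event type in attribute `"killed"`.
#'
#' Uses R's global random number generator.
#'
#' @param n Number of trials.
#' @param T_A Mean attachment lifetime, min.
#' @param dt Step size, min.
#' @param kill_rate Kill rate at `p = 1`, 1/min (0 disables killing).
#' @param p Target oncoprotein expression.
#' @return Numeric vector of lifetimes, min (attribute `"killed"` flags
#'   which trials ended in a kill when `kill_rate > 0`).
#' @export
simulate_attachment_lifetimes <- function(n, T_A = 60, dt = 0.1,
                                          kill_rate = 0, p = 1) {
  pd <- min(1, dt / T_A)
  if (kill_rate <= 0) return((rgeom(n, pd) + 1) * dt)
  pk <- min(1, kill_rate * p * dt)
  # kill is evaluated first within a step: P(event) and P(kill | event)
  pe <- pk + (1 - pk) * pd
  steps <- rgeom(n, pe) + 1
  killed <- stats::runif(n) < pk / pe
  structure(steps * dt, killed = killed)
}

#' Simulate times to kill
#'
#' Time until an always-attached immune cell triggers apoptosis in a target
#' with oncoprotein `p`: per-step success probability
#' `min(1, kill_rate * p * dt)`, so the mean is `1 / (kill_rate * p)` --
#' the kill hazard scales linearly in the target's oncoprotein expression.
#'
#' @param n Number of trials.
#' @param kill_rate Kill rate at `p = 1`, 1/min.
#' @param p Target oncoprotein expression.
#' @param dt Step size, min.
#' @return Numeric vector of kill times, min.
#' @export
simulate_kill_times <- function(n, kill_rate = 0.06, p = 1, dt = 0.1) {
  pk <- min(1, kill_rate * p * dt)
  (rgeom(n, pk) + 1) * dt
}

#' Configure a cancer-immune experiment
#'
#' The tumor-immune study configuration: a heterogeneous immunogenic tumor
#' (oncoprotein ~ Normal(1, 0.3) truncated to \[0, 2\]) grows under oxygen
#' limitation while secreting an immunostimulatory factor; immune cells are
#' introduced on a shell just outside the tumor at `introduction_time` and
#' hunt by biased chemotaxis with stochastic attach/kill/detach dynamics.
#'
#' @param tumor_cells Initial tumor cell count.
#' @param immune_cells Immune cells introduced.
#' @param introduction_time Immune introduction time, min.
#' @param duration Total simulated time, min.
#' @param r_A,T_A,bias,kill_rate,speed,persistence_time See
#'   [immune_params()].
#' @param boundary_oxygen Dirichlet oxygen tension at the domain boundary,
#'   mmHg.
#' @param domain_edge Square domain edge, um.
#' @param dimensions 2 or 3.
#' @param mean_p,sd_p Oncoprotein distribution parameters.
#' @param save_interval Snapshot cadence, min (`NULL`: initial and final
#'   only).
#' @param seed Integer seed.
#' @return A list of class `immune_config`.
#' @export
immune_config <- function(tumor_cells = 1000, immune_cells = 300,
                          introduction_time = 0, duration = 1440,
                          r_A = 0.2, T_A = 60, bias = 0.5, kill_rate = 0.06,
                          speed = 1, persistence_time = 10,
                          boundary_oxygen = 38, domain_edge = 1200,
                          dimensions = 2, mean_p = 1, sd_p = 0.3,
                          save_interval = NULL, seed = 1L) {
  structure(as.list(environment()), class = "immune_config")
}

#' Run the cancer-immune interaction model
#'
#' Builds the two-substrate microenvironment (oxygen diffusing in from the
#' boundary; the immunostimulatory factor secreted by live tumor cells with
#' D = 1000 um^2/min and decay 0.02/min, giving a gradient spanning a
#' few-hundred-um tumor with a flat plateau at its center), initializes the
#' heterogeneous tumor, and runs the combined dynamics.
#'
#' @param config An [immune_config()].
#' @return An object of class `immune_run`: the underlying `tissue_sim` plus
#'   `final_live_tumor` and the live-tumor time series.
#' @examples
#' \donttest{
#' run <- run_cancer_immune(immune_config(tumor_cells = 50,
#'                                        immune_cells = 20,
#'                                        duration = 120, seed = 7))
#' run$final_live_tumor
#' }
#' @export
run_cancer_immune <- function(config) {
  stopifnot(inherits(config, "immune_config"))
  edge <- config$domain_edge
  nside <- max(3L, as.integer(round(edge / 20)))
  nz <- if (config$dimensions == 3) nside else 1L
  mesh <- create_mesh(nside, nside, nz,
                      origin = c(-edge / 2, -edge / 2,
                                 if (config$dimensions == 3) -edge / 2 else -10))
  subs <- substrate_system(
    c("oxygen", "chemokine"),
    D = c(1e5, 1000), lambda = c(0.1, 0.02),
    boundary = c("dirichlet", "noflux"),
    boundary_value = c(config$boundary_oxygen, 0))
  set.seed(config$seed)
  cells <- init_heterogeneous_tumor(config$tumor_cells,
                                    mean_p = config$mean_p,
                                    sd_p = config$sd_p,
                                    dimensions = config$dimensions)
  imm <- immune_params(n = config$immune_cells,
                       introduction_time = config$introduction_time,
                       r_A = config$r_A, T_A = config$T_A,
                       bias = config$bias, kill_rate = config$kill_rate,
                       speed = config$speed,
                       persistence_time = config$persistence_time)
  cfg <- tissue_config(mesh, subs, cells,
                       immune = imm,
                       duration = config$duration,
                       save_interval = config$save_interval,
                       oxygen = "oxygen", chemokine = "chemokine",
                       seed = config$seed)
  sim <- simulate_tissue(cfg)
  ts <- sim$timeseries
  structure(c(sim,
              list(final_live_tumor = ts$live_tumor[nrow(ts)],
                   live_tumor = ts[, c("time", "live_tumor")],
                   study = config)),
            class = c("immune_run", "tissue_sim"))
}

#' @export
print.immune_run <- function(x, ...) {
  s <- x$study
  cat(sprintf(
    "Cancer-immune run: %d tumor + %d immune cells, r_A=%g/min, T_A=%g min, b=%g\n",
    s$tumor_cells, s$immune_cells, s$r_A, s$T_A, s$bias))
  cat(sprintf("  live tumor cells at t=%g min: %d\n",
              s$duration, x$final_live_tumor))
  invisible(x)
}
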