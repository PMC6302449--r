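#' Mechanical interaction velocities
#'
#' Computes the pairwise adhesion/repulsion velocity of every cell using a
#' uniform spatial hash whose bin edge is at least the maximum mechanical
#' interaction distance, so the 3 x 3 x 3 bin stencil is guaranteed to
#' contain every interacting partner. For a pair at center distance `d` with
#' radii `R_i`, `R_j`:
#' repulsion of magnitude `repulsion * (1 - d / (R_i + R_j))^2` acts when the
#' cells overlap, and adhesion of magnitude `adhesion * (1 - d / d_max)^2`
#' acts within `d_max = factor * (R_i + R_j)`, both directed along the
#' center line. Coincident centers are pushed apart along a deterministic
#' pseudo-random direction derived from the pair indices (never a division
#' by zero).
#'
#' @param position n x 3 matrix of cell centers (micrometres).
#' @param radius Cell radii (micrometres).
#' @param repulsion Repulsion strength, um/min (default 10).
#' @param adhesion Adhesion strength, um/min (default 0.4).
#' @param max_adhesion_factor Interaction range as a multiple of the radius
#'   sum (default 1.25, >= 1).
#' @param motility Optional n x 3 matrix of motility velocities added to the
#'   mechanical terms.
#' @param attached_pairs Optional 2-column integer matrix of (1-based) index
#'   pairs whose adhesion is multiplied by `attachment_multiplier` (used for
#'   tight immune-target adhesions).
#' @param attachment_multiplier Adhesion boost for attached pairs
#'   (default 10).
#' @param three_d Logical; use 3-D directions for coincident-center pushes.
#' @return n x 3 matrix of velocities (um/min).
#' @export
compute_velocities <- function(position, radius, repulsion = 10,
                               adhesion = 0.4, max_adhesion_factor = 1.25,
                               motility = NULL, attached_pairs = NULL,
                               attachment_multiplier = 10, three_d = TRUE) {
  position <- matrix(as.numeric(position), ncol = 3)
  if (max_adhesion_factor < 1)
    stop("configuration error: max_adhesion_factor must be >= 1")
  bp <- NULL
  if (!is.null(attached_pairs) && nrow(attached_pairs) > 0)
    bp <- matrix(as.integer(attached_pairs) - 1L, ncol = 2)
  cpp_compute_velocities(position, as.numeric(radius), repulsion, adhesion,
                         max_adhesion_factor, motility, bp,
                         attachment_multiplier, three_d)
}

#' Adams-Bashforth position update
#'
#' Second-order Adams-Bashforth step `x <- x + dt * (1.5 v - 0.5 v_prev)`;
#' rows with no previous velocity (a cell's first step) fall back to forward
#' Euler. Exact for constant velocity.
#'
#' @param position n x 3 matrix of positions.
#' @param velocity n x 3 matrix of current velocities.
#' @param previous_velocity Optional n x 3 matrix; rows of `NA` (or the
#'   whole argument `NULL`) mark first steps.
#' @param dt Time step, min.
#' @return n x 3 matrix of updated positions.
#' @export
update_positions <- function(position, velocity, previous_velocity = NULL,
                             dt) {
  position <- matrix(as.numeric(position), ncol = 3)
  velocity <- matrix(as.numeric(velocity), ncol = 3)
  if (is.null(previous_velocity))
    return(position + dt * velocity)
  previous_velocity <- matrix(as.numeric(previous_velocity), ncol = 3)
  first <- !stats::complete.cases(previous_velocity)
  out <- position + dt * (1.5 * velocity - 0.5 * previous_velocity)
  if (any(first))
    out[first, ] <- position[first, , drop = FALSE] +
      dt * velocity[first, , drop = FALSE]
  out
}

#' Oxygen-dependent cycle entry rate
#'
#' The rate at which a live tumor cell enters the cell cycle:
#' `p * rate_max * clamp((pO2 - necrosis_threshold) /
#' (saturation - necrosis_threshold), 0, 1)`. Proliferation saturates above
#' the physioxic saturation tension (default 38 mmHg) and vanishes at the
#' necrosis threshold; the oncoprotein expression `p` scales the rate
#' linearly.
#'
#' @param p Oncoprotein expression (dimensionless).
#' @param pO2 Local oxygen tension, mmHg.
#' @param rate_max Maximum cycle entry rate at `p = 1`, 1/min.
#' @param necrosis_threshold Oxygen tension below which cells necrose, mmHg.
#' @param saturation Oxygen tension above which proliferation saturates,
#'   mmHg.
#' @return Cycle entry rate, 1/min (vectorized).
#' @export
cycle_entry_rate <- function(p, pO2, rate_max, necrosis_threshold = 5,
                             saturation = 38) {
  ramp <- pmin(pmax((pO2 - necrosis_threshold) /
                      (saturation - necrosis_threshold), 0), 1)
  p * rate_max * ramp
}

#' Cell radius from volume
#'
#' Cells are spheres: \eqn{r = (3V / 4\pi)^{1/3}}.
#' @param volume Cell volume, um^3.
#' @return Radius, um.
#' @export
cell_radius <- function(volume) (3 * volume / (4 * pi))^(1 / 3)

#' Tumor phenotype parameters
#'
#' Defaults describe a slowly cycling, oxygen-limited epithelial-like tumor
#' cell: cycle entry saturates at 3.5e-4/min (about one division per two
#' days at full oxygenation), background apoptosis 7e-5/min, deterministic
#' necrosis below 5 mmHg. Dead cells shrink exponentially (half-life 30 min
#' apoptotic, 720 min necrotic -- necrotic cells lose volume slowly) and are
#' removed below 5% of their volume at death.
#'
#' @param cycle_entry_rate_max Max cycle entry rate at `p = 1`, 1/min.
#' @param apoptosis_rate Background apoptosis rate, 1/min.
#' @param necrosis_threshold Necrosis oxygen threshold, mmHg.
#' @param oxygen_saturation Proliferation saturation tension, mmHg.
#' @param oxygen_uptake Per-cell oxygen uptake rate, 1/min.
#' @param chemokine_secretion Immunostimulatory-factor secretion rate, 1/min
#'   (live tumor cells only).
#' @param chemokine_saturation Saturation density of the secreted factor.
#' @param volume Target (and initial) cell volume, um^3.
#' @param volume_relax_rate Relaxation rate of live-cell volume back to
#'   target after division, 1/min.
#' @param apoptotic_halflife,necrotic_halflife Volume-loss half-lives of
#'   dead cells, min.
#' @param removal_fraction Fraction of the at-death volume below which a
#'   dead cell is removed.
#' @return A list of class `tumor_phenotype`.
#' @export
tumor_phenotype <- function(cycle_entry_rate_max = 3.5e-4,
                            apoptosis_rate = 7e-5,
                            necrosis_threshold = 5,
                            oxygen_saturation = 38,
                            oxygen_uptake = 2,
                            chemokine_secretion = 10,
                            chemokine_saturation = 1,
                            volume = 2494,
                            volume_relax_rate = 0.01,
                            apoptotic_halflife = 30,
                            necrotic_halflife = 720,
                            removal_fraction = 0.05) {
  p <- as.list(environment())
  if (any(unlist(p) < 0)) stop("configuration error: rates must be >= 0")
  class(p) <- "tumor_phenotype"
  p
}

#' Mechanics parameters
#'
#' @param repulsion Repulsion strength, um/min.
#' @param adhesion Adhesion strength, um/min.
#' @param max_adhesion_factor Interaction range factor (>= 1).
#' @param attach_adhesion_mult Adhesion multiplier for attached
#'   immune-target pairs ("tight adhesions").
#' @return A list of class `mechanics_params`.
#' @export
mechanics_params <- function(repulsion = 10, adhesion = 0.4,
                             max_adhesion_factor = 1.25,
                             attach_adhesion_mult = 10) {
  if (max_adhesion_factor < 1)
    stop("configuration error: max_adhesion_factor must be >= 1")
  structure(list(repulsion = repulsion, adhesion = adhesion,
                 max_adhesion_factor = max_adhesion_factor,
                 attach_adhesion_mult = attach_adhesion_mult),
            class = "mechanics_params")
}
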