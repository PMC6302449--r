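#' Bulk source/uptake sub-step
#'
#' Advances the per-voxel linear source/uptake ordinary differential
#' equations one backward-Euler step: for each voxel and substrate,
#' \deqn{\rho \leftarrow \frac{\rho + \Delta t\, S \rho^*}{1 + \Delta t (S + U)},}
#' which is unconditionally stable and first-order accurate, with fixed
#' point \eqn{S\rho^*/(S+U)}.
#'
#' @param field A [new_field()] matrix.
#' @param substrates The matching [substrate_system()].
#' @param dt Time step, min (> 0).
#' @return The updated field.
#' @export
step_bulk_supply <- function(field, substrates, dt) {
  stopifnot(inherits(substrates, "substrate_system"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  field_check(field, substrates)
  out <- cpp_bulk_supply(unclass(field), substrates$bulk_S, substrates$bulk_U,
                         substrates$rho_star, dt)
  field_like(out, field)
}

#' Cell-centered source/uptake sub-step
#'
#' Applies each cell's secretion/uptake to the voxel containing its center
#' (the Dirac-delta formulation): the backward-Euler update of
#' [step_bulk_supply()] restricted to that voxel, with the cell's rates
#' scaled by `volume / voxel_volume` to convert the point source into a
#' density rate. Cells sharing a voxel are applied sequentially in ascending
#' cell-id order, which keeps the update deterministic.
#'
#' @param field A [new_field()] matrix.
#' @param mesh The mesh the field lives on.
#' @param exchanges A cell-exchange table from [cell_exchange()].
#' @param dt Time step, min (> 0).
#' @return The updated field.
#' @export
step_cell_exchange <- function(field, mesh, exchanges, dt) {
  stopifnot(inherits(mesh, "cartesian_mesh"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (length(exchanges$id) == 0L) return(field)
  ord <- order(exchanges$id)
  out <- cpp_cell_exchange(unclass(field), mesh_to_list(mesh),
                           exchanges$position[ord, , drop = FALSE],
                           exchanges$volume[ord],
                           exchanges$S[ord, , drop = FALSE],
                           exchanges$U[ord, , drop = FALSE],
                           exchanges$rho_star[ord, , drop = FALSE], dt)
  field_like(out, field)
}

#' Build a cell-exchange table
#'
#' @param id Integer cell ids (unique).
#' @param position n x 3 matrix of cell centers (micrometres).
#' @param volume Cell volumes, um^3 (> 0).
#' @param S,U n x m matrices of per-substrate secretion/uptake rates, 1/min
#'   (scalars and vectors are recycled).
#' @param rho_star n x m per-cell saturation densities.
#' @param m Number of substrates (used to recycle scalar rates).
#' @return A list suitable for [step_cell_exchange()].
#' @export
cell_exchange <- function(id, position, volume, S, U, rho_star, m = NULL) {
  position <- matrix(as.numeric(position), ncol = 3)
  n <- nrow(position)
  if (is.null(m)) m <- if (is.matrix(S)) ncol(S) else length(S)
  as_mat <- function(x) {
    if (is.matrix(x)) x else matrix(rep_len(as.numeric(x), m), n, m, byrow = TRUE)
  }
  S <- as_mat(S); U <- as_mat(U); rho_star <- as_mat(rho_star)
  if (any(S < 0) || any(U < 0)) stop("secretion/uptake rates must be >= 0")
  if (any(volume <= 0)) stop("cell volumes must be > 0")
  list(id = as.integer(id), position = position,
       volume = as.numeric(volume), S = S, U = U, rho_star = rho_star)
}

#' Precompute the Thomas forward sweeps for the LOD diffusion step
#'
#' The implicit diffusion-decay step solves one tridiagonal system per grid
#' strip, per axis, per substrate. The forward-elimination coefficients
#' depend only on the mesh, the diffusion coefficients, the decay rates and
#' the time step -- not on the field -- so they are computed once and cached.
#' Decay is apportioned equally across the active axes (lambda/3 per axis in
#' 3-D, lambda/2 in 2-D) so each 1-D system stays tridiagonal.
#'
#' @param mesh A [create_mesh()] object.
#' @param substrates A [substrate_system()].
#' @param dt Diffusion time step, min (> 0).
#' @return An object of class `thomas_cache`, valid for this exact
#'   (mesh, substrates, dt) combination.
#' @export
precompute_thomas <- function(mesh, substrates, dt) {
  stopifnot(inherits(mesh, "cartesian_mesh"),
            inherits(substrates, "substrate_system"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  cc <- cpp_thomas_cache(mesh_to_list(mesh), substrates$D, substrates$lambda,
                         dt)
  structure(list(mesh = mesh, substrates = substrates, dt = dt, sweeps = cc),
            class = "thomas_cache")
}

#' LOD implicit diffusion-decay sub-step
#'
#' Performs the locally one-dimensional step: sequential implicit solves
#' along x, then y, then z (active axes only), each a tridiagonal solve via
#' the cached Thomas forward sweep. No-flux boundaries use a zero-gradient
#' closure in the end rows; Dirichlet boundaries are enforced by pinning the
#' domain-boundary voxels to the configured value after each axis solve.
#'
#' @param field A [new_field()] matrix.
#' @param cache A [precompute_thomas()] cache. The cache must have been
#'   built for this field's mesh and substrate system; a mismatch raises a
#'   cache-invalid error.
#' @return The updated field.
#' @export
step_diffusion_decay <- function(field, cache) {
  if (!inherits(cache, "thomas_cache"))
    stop("cache-invalid error: not a thomas_cache")
  mesh <- cache$mesh; subs <- cache$substrates
  if (nrow(field) != mesh$n_voxels || ncol(field) != subs$m)
    stop("cache-invalid error: cache was built for a different mesh/substrate system")
  fa <- attr(field, "substrates")
  if (!is.null(fa) && (!identical(fa$D, subs$D) ||
                       !identical(fa$lambda, subs$lambda)))
    stop("cache-invalid error: substrate parameters changed since the cache was built")
  out <- cpp_diffusion_decay(unclass(field), mesh_to_list(mesh), subs$D,
                             subs$lambda,
                             as.integer(subs$boundary == "dirichlet"),
                             subs$boundary_value, cache$dt)
  if (!all(is.finite(out))) stop("solver produced non-finite densities")
  field_like(out, field)
}

#' Full operator-split biotransport step
#'
#' One first-order operator-splitting step of the multi-substrate
#' reaction-diffusion system: the bulk source/uptake sub-step first,
#' followed by the cell-centered sources/uptakes, followed by the implicit
#' LOD diffusion-decay solve -- in exactly that order (the sub-steps do not
#' commute).
#'
#' @param field A [new_field()] matrix.
#' @param mesh The mesh.
#' @param substrates The substrate system.
#' @param exchanges Optional [cell_exchange()] table (NULL for no cells).
#' @param dt Time step, min.
#' @param cache Optional [precompute_thomas()] cache (built on the fly when
#'   omitted).
#' @return The updated field.
#' @export
diffusion_step <- function(field, mesh, substrates, exchanges = NULL, dt,
                           cache = NULL) {
  if (is.null(cache)) cache <- precompute_thomas(mesh, substrates, dt)
  if (!isTRUE(all.equal(cache$dt, dt)))
    stop("cache-invalid error: cache dt differs from requested dt")
  field <- step_bulk_supply(field, substrates, dt)
  if (!is.null(exchanges))
    field <- step_cell_exchange(field, mesh, exchanges, dt)
  step_diffusion_decay(field, cache)
}
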