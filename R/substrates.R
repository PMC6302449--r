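#' Define the diffusing substrate system
#'
#' Each substrate is a diffusing chemical density field with its own
#' diffusion coefficient, decay rate, optional bulk source/uptake toward a
#' saturation density, and a boundary condition: `"dirichlet"` (the domain
#' boundary voxels are held at `boundary_value`, the far-field semantics used
#' for oxygen supplied from outside the tissue) or `"noflux"` (zero-gradient
#' closure).
#'
#' @param names Character vector of substrate identifiers.
#' @param D Diffusion coefficients, um^2/min (recycled; >= 0).
#' @param lambda Decay rates, 1/min (>= 0).
#' @param bulk_S,bulk_U Bulk source and uptake rates, 1/min (>= 0).
#' @param rho_star Saturation densities (model units) the bulk source pushes
#'   toward.
#' @param boundary Character vector, `"noflux"` or `"dirichlet"` per
#'   substrate.
#' @param boundary_value Dirichlet value per substrate (ignored for noflux).
#' @param initial Initial uniform field value per substrate; defaults to the
#'   Dirichlet value where one is set, else 0.
#' @return An object of class `substrate_system`.
#' @examples
#' oxy <- substrate_system("oxygen", D = 1e5, lambda = 0.1,
#'                         boundary = "dirichlet", boundary_value = 38)
#' @export
substrate_system <- function(names, D, lambda = 0, bulk_S = 0, bulk_U = 0,
                             rho_star = 1, boundary = "noflux",
                             boundary_value = 0, initial = NULL) {
  m <- length(names)
  if (m < 1L) stop("configuration error: at least one substrate required")
  rec <- function(x) rep_len(as.numeric(x), m)
  D <- rec(D); lambda <- rec(lambda); bulk_S <- rec(bulk_S)
  bulk_U <- rec(bulk_U); rho_star <- rec(rho_star)
  boundary_value <- rec(boundary_value)
  boundary <- rep_len(boundary, m)
  if (!all(boundary %in% c("noflux", "dirichlet")))
    stop("configuration error: boundary must be 'noflux' or 'dirichlet'")
  if (any(D < 0) || any(lambda < 0) || any(bulk_S < 0) || any(bulk_U < 0))
    stop("configuration error: D, lambda, bulk_S, bulk_U must be >= 0")
  if (is.null(initial))
    initial <- ifelse(boundary == "dirichlet", boundary_value, 0)
  initial <- rec(initial)
  s <- list(names = as.character(names), D = D, lambda = lambda,
            bulk_S = bulk_S, bulk_U = bulk_U, rho_star = rho_star,
            boundary = boundary, boundary_value = boundary_value,
            initial = initial, m = m)
  class(s) <- "substrate_system"
  s
}

#' @export
print.substrate_system <- function(x, ...) {
  cat("Substrate system:\n")
  for (i in seq_len(x$m))
    cat(sprintf("  %s: D=%g um^2/min, lambda=%g/min, boundary=%s%s\n",
                x$names[i], x$D[i], x$lambda[i], x$boundary[i],
                if (x$boundary[i] == "dirichlet")
                  sprintf("(%g)", x$boundary_value[i]) else ""))
  invisible(x)
}

# internal list form for C++
substrates_to_list <- function(s) {
  list(D = s$D, lambda = s$lambda, bulk_S = s$bulk_S, bulk_U = s$bulk_U,
       rho_star = s$rho_star,
       btype = as.integer(s$boundary == "dirichlet"),
       bval = s$boundary_value, init = s$initial)
}

#' Create a field state over a mesh
#'
#' A field state holds one density value per (voxel, substrate) pair, stored
#' as a matrix with voxels in rows (x fastest, then y, then z) and substrates
#' in columns.
#'
#' @param mesh A [create_mesh()] object.
#' @param substrates A [substrate_system()].
#' @param values Optional initial values: a scalar, a per-substrate vector,
#'   or a full `n_voxels x m` matrix. Defaults to the substrate `initial`
#'   values.
#' @return Numeric matrix of class `field_state` with the mesh and substrate
#'   system kept as attributes.
#' @export
new_field <- function(mesh, substrates, values = NULL) {
  stopifnot(inherits(mesh, "cartesian_mesh"),
            inherits(substrates, "substrate_system"))
  nv <- mesh$n_voxels
  if (is.null(values)) values <- substrates$initial
  if (is.matrix(values)) {
    if (nrow(values) != nv || ncol(values) != substrates$m)
      stop("configuration error: field matrix shape mismatch")
    f <- values
  } else {
    f <- matrix(rep(rep_len(as.numeric(values), substrates$m), each = nv),
                nrow = nv)
  }
  colnames(f) <- substrates$names
  structure(f, mesh = mesh, substrates = substrates,
            class = c("field_state", "matrix", "array"))
}

field_check <- function(field, substrates) {
  if (!is.matrix(field)) stop("configuration error: field must be a matrix")
  if (ncol(field) != substrates$m)
    stop("configuration error: field/substrate count mismatch")
  invisible(TRUE)
}

# reattach field attributes after a C++ round trip
field_like <- function(values, field) {
  structure(values, mesh = attr(field, "mesh"),
            substrates = attr(field, "substrates"),
            dimnames = dimnames(field),
            class = class(field))
}
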