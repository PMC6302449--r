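#' Create a Cartesian voxel mesh
#'
#' The mesh is the shared spatial scaffold for the diffusion solver and the
#' cell agents: a regular grid of `nx * ny * nz` box voxels with edge lengths
#' `dx`, `dy`, `dz` (micrometres) anchored at `origin` (the lower corner).
#' Two-dimensional simulations are represented as an `nz = 1` slab of
#' thickness `dz`, so densities and volumes keep their 3-D units.
#'
#' Voxel `(i, j, k)` (0-based) spans the half-open interval
#' `[origin + i*dx, origin + (i+1)*dx)` along x (likewise y, z), which makes
#' the position-to-voxel map unambiguous for positions sitting exactly on a
#' voxel face.
#'
#' @param nx,ny,nz Voxel counts per axis (>= 1); `nz = 1` encodes 2-D.
#' @param dx,dy,dz Voxel edge lengths in micrometres (> 0). Default 20.
#' @param origin Numeric length-3 lower-corner coordinates (micrometres).
#' @return An object of class `cartesian_mesh` with fields `nx, ny, nz, dx,
#'   dy, dz, origin`, plus the derived `voxel_volume` and `n_voxels`.
#' @examples
#' m <- create_mesh(10, 10, 1)
#' m$n_voxels      # 100
#' m$voxel_volume  # 8000
#' @export
create_mesh <- function(nx, ny, nz = 1L, dx = 20, dy = 20, dz = 20,
                        origin = c(0, 0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(is.na(c(nx, ny, nz))) || nx < 1L || ny < 1L || nz < 1L)
    stop("configuration error: voxel counts must be >= 1")
  if (!all(is.finite(c(dx, dy, dz))) || dx <= 0 || dy <= 0 || dz <= 0)
    stop("configuration error: voxel edge lengths must be > 0")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("configuration error: origin must be a finite length-3 vector")
  m <- list(nx = nx, ny = ny, nz = nz,
            dx = dx, dy = dy, dz = dz,
            origin = as.numeric(origin),
            voxel_volume = dx * dy * dz,
            n_voxels = nx * ny * nz)
  class(m) <- "cartesian_mesh"
  m
}

#' @export
print.cartesian_mesh <- function(x, ...) {
  cat(sprintf("Cartesian mesh: %d x %d x %d voxels (%g x %g x %g um each)\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz))
  cat(sprintf("  domain: [%g, %g] x [%g, %g] x [%g, %g] um, %d voxels\n",
              x$origin[1], x$origin[1] + x$nx * x$dx,
              x$origin[2], x$origin[2] + x$ny * x$dy,
              x$origin[3], x$origin[3] + x$nz * x$dz, x$n_voxels))
  invisible(x)
}

#' Voxel containing a position
#'
#' Maps a position to the (0-based) index triple of the half-open voxel
#' interval that contains it; positions exactly on an interior voxel face
#' belong to the upper voxel (lower-inclusive convention).
#'
#' @param mesh A [create_mesh()] object.
#' @param position Numeric length-3 position (micrometres).
#' @return Integer vector `c(i, j, k)` (0-based), with the 1-based linear
#'   index (x fastest) in attribute `"linear"`.
#' @examples
#' m <- create_mesh(10, 10, 1)
#' voxel_containing(m, c(20, 0, 0))  # c(1, 0, 0)
#' @export
voxel_containing <- function(mesh, position) {
  stopifnot(inherits(mesh, "cartesian_mesh"))
  if (length(position) != 3L || !all(is.finite(position)))
    stop("position must be a finite length-3 vector")
  rel <- (position - mesh$origin) / c(mesh$dx, mesh$dy, mesh$dz)
  ijk <- as.integer(floor(rel))
  hi <- c(mesh$nx, mesh$ny, mesh$nz)
  if (any(ijk < 0L) || any(ijk >= hi))
    stop("out-of-domain error: position lies outside the mesh")
  structure(ijk, linear = ijk[1] + mesh$nx * (ijk[2] + mesh$ny * ijk[3]) + 1L)
}

#' Voxel center coordinates
#'
#' @param mesh A [create_mesh()] object.
#' @param ijk Integer 0-based voxel index triple.
#' @return Numeric length-3 center position (micrometres).
#' @export
voxel_center <- function(mesh, ijk) {
  stopifnot(inherits(mesh, "cartesian_mesh"), length(ijk) == 3L)
  mesh$origin + (as.numeric(ijk) + 0.5) * c(mesh$dx, mesh$dy, mesh$dz)
}

# internal: plain list form handed to C++
mesh_to_list <- function(mesh) {
  list(nx = mesh$nx, ny = mesh$ny, nz = mesh$nz,
       dx = mesh$dx, dy = mesh$dy, dz = mesh$dz, origin = mesh$origin)
}
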