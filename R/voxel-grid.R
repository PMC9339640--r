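#' Voxelized density grid
#'
#' A `voxel_grid` is the dose-calculation substrate: a 3-D scalar density
#' field (g/cm^3) on a regular grid. World coordinates are in mm; `origin`
#' is the world coordinate of the *center* of voxel `[1,1,1]`, indices are
#' stored 1-based in R. Axes are ordered x (left-right), y
#' (ventro-dorsal) and z (cranio-caudal).
#'
#' @param dims integer vector of length 3, voxels per axis (each >= 8).
#' @param spacing numeric length 3, voxel spacing in mm (all > 0).
#' @param origin numeric length 3, world position (mm) of the first voxel
#'   center.
#' @param density 3-D numeric array of densities in g/cm^3 (all >= 0), or a
#'   single number to fill the grid.
#' @return An object of class `voxel_grid` with fields `dims`, `spacing`,
#'   `origin`, `density`.
#' @export
voxel_grid <- function(dims, spacing, origin = c(0, 0, 0), density = 1) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(dims < 8L)) stop("voxel_grid: all dims must be >= 8")
  if (any(spacing <= 0)) stop("voxel_grid: all spacings must be > 0")
  if (length(density) == 1L) density <- array(density, dim = dims)
  if (!identical(dim(density), dims)) {
    stop("voxel_grid: density array dims do not match `dims`")
  }
  if (any(density < 0)) stop("voxel_grid: densities must be >= 0")
  structure(
    list(dims = dims, spacing = as.numeric(spacing),
         origin = as.numeric(origin), density = density),
    class = "voxel_grid"
  )
}

#' Voxel-center world coordinates along one axis
#' @param grid a `voxel_grid`
#' @param axis 1, 2 or 3
#' @return numeric vector of length `dims[axis]` (mm)
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' Volume of one voxel in mm^3
#' @param grid a `voxel_grid`
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = "/"),
      " mm\n  origin (", paste(format(x$origin), collapse = ", "),
      ") mm; density range [",
      format(min(x$density)), ", ", format(max(x$density)), "] g/cm^3\n",
      sep = "")
  invisible(x)
}

#' Named set of binary structure masks on a shared grid
#'
#' @param grid a `voxel_grid` (only its geometry is retained).
#' @param masks named list of logical 3-D arrays, each matching `grid$dims`.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(grid, masks) {
  stopifnot(inherits(grid, "voxel_grid"), is.list(masks), !is.null(names(masks)))
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), grid$dims)) {
      stop("structure_set: mask '", nm, "' is not a logical array on the grid")
    }
  }
  structure(list(grid = grid, masks = masks), class = "structure_set")
}

#' Fetch one mask from a structure set
#' @param structures a `structure_set`
#' @param name structure name
#' @return logical 3-D array
#' @export
get_mask <- function(structures, name) {
  if (!name %in% names(structures$masks)) {
    stop("structure '", name, "' not present in the structure set")
  }
  structures$masks[[name]]
}

#' @export
print.structure_set <- function(x, ...) {
  n <- vapply(x$masks, sum, numeric(1))
  cat("<structure_set> on ", paste(x$grid$dims, collapse = "x"), " grid\n", sep = "")
  for (nm in names(n)) cat(sprintf("  %-10s %8d voxels\n", nm, as.integer(n[[nm]])))
  invisible(x)
}

# internal: world coordinates of every voxel center as three arrays
grid_coordinate_arrays <- function(grid) {
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2); zs <- grid_axis(grid, 3)
  d <- grid$dims
  list(
    x = array(rep(xs, times = d[2] * d[3]), dim = d),
    y = array(rep(rep(ys, each = d[1]), times = d[3]), dim = d),
    z = array(rep(zs, each = d[1] * d[2]), dim = d)
  )
}
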