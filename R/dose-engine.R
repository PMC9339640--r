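#' Radiological path length between two world points
#'
#' Exact Siddon-style line integral of density over the voxels traversed by
#' the segment from `src` to `dst`, in g/cm^2. Symmetric in its endpoints;
#' returns 0 for segments that miss the grid or have zero length.
#'
#' @param grid a [voxel_grid()]
#' @param src,dst world points, mm
#' @return areal density in g/cm^2
#' @export
radiological_path <- function(grid, src, dst) {
  stopifnot(length(src) == 3L, length(dst) == 3L)
  cpp_radiological_path(grid$density, grid$dims, grid$spacing, grid$origin,
                        as.numeric(src), as.numeric(dst))
}

# materials default: everything soft tissue
default_materials <- function(grid, materials) {
  if (is.null(materials)) array(0L, dim = grid$dims) else materials
}

enh_vector <- function(attenuation) {
  as.numeric(attenuation$enhancement[c("soft", "lung", "bone")])
}

#' Dose column of a single beamlet
#'
#' Computes the dose per unit weight of one beamlet of a field: primary
#' attenuation along the exact radiological path from the source, divergent
#' inverse-square falloff, per-medium enhancement, and the Gaussian lateral
#' kernel evaluated in the isocenter plane.
#'
#' @param grid a [voxel_grid()]
#' @param geometry a [beam_geometry()]
#' @param attenuation an [attenuation_model()]
#' @param index beamlet index, 1-based column-major over the `(n1, n2)`
#'   lattice (`i` along `e1` fastest)
#' @param materials optional integer array of material ids (0 soft, 1 lung,
#'   2 bone); default all soft tissue
#' @return 3-D numeric array of dose (Gy per unit weight)
#' @export
beamlet_dose <- function(grid, geometry, attenuation, index, materials = NULL) {
  nb <- geometry$n1 * geometry$n2
  if (index < 1 || index > nb) {
    stop("beamlet index ", index, " out of range 1..", nb)
  }
  i <- (index - 1) %% geometry$n1
  j <- (index - 1) %/% geometry$n1
  b <- geometry$beamlet_mm
  materials <- default_materials(grid, materials)
  support <- seq_len(prod(grid$dims)) - 1L
  tr <- cpp_influence_field(
    grid$density, grid$dims, grid$spacing, grid$origin,
    as.integer(support), as.integer(materials), enh_vector(attenuation),
    geometry$source, geometry$isocenter, geometry$e1, geometry$e2,
    geometry$sid, 1L, 1L, b,
    geometry$offset[1] + i * b, geometry$offset[2] + j * b,
    attenuation$mu_water, attenuation$sigma_mm,
    attenuation$cutoff_sigma * attenuation$sigma_mm,
    attenuation$calibration)
  out <- array(0, dim = grid$dims)
  out[tr$i + 1L] <- tr$x
  out
}

#' Assemble the sparse dose-influence matrix over a set of fields
#'
#' One column per beamlet of every field, rows restricted to the voxels of
#' `support_mask` (typically body plus margin-dilated PTV). Entries below
#' `sparsity_floor` times their column maximum are dropped.
#'
#' @param grid a [voxel_grid()]
#' @param geometries list of [beam_geometry()] objects (>= 1)
#' @param attenuation an [attenuation_model()]
#' @param support_mask logical array selecting the voxels carried by the
#'   matrix (must be nonempty)
#' @param materials optional material-id array (see [beamlet_dose()])
#' @return object of class `dose_influence`: fields `D` (dgCMatrix,
#'   support x beamlets), `support` (1-based voxel indices), `dims`,
#'   `fields` (per-field geometry and column ranges), `attenuation`
#' @export
assemble_influence <- function(grid, geometries, attenuation, support_mask,
                               materials = NULL) {
  stopifnot(length(geometries) >= 1)
  if (inherits(geometries, "beam_geometry")) geometries <- list(geometries)
  support <- which(support_mask)
  if (length(support) == 0L) stop("empty voxel support")
  materials <- default_materials(grid, materials)
  cut <- attenuation$cutoff_sigma * attenuation$sigma_mm

  blocks <- vector("list", length(geometries))
  fields <- vector("list", length(geometries))
  col0 <- 0L
  for (f in seq_along(geometries)) {
    g <- geometries[[f]]
    tr <- cpp_influence_field(
      grid$density, grid$dims, grid$spacing, grid$origin,
      as.integer(support - 1L), as.integer(materials), enh_vector(attenuation),
      g$source, g$isocenter, g$e1, g$e2, g$sid, g$n1, g$n2, g$beamlet_mm,
      g$offset[1], g$offset[2],
      attenuation$mu_water, attenuation$sigma_mm, cut,
      attenuation$calibration)
    blocks[[f]] <- list(i = tr$i + 1L, j = tr$j + col0 + 1L, x = tr$x)
    fields[[f]] <- list(geometry = g, n1 = g$n1, n2 = g$n2,
                        cols = col0 + seq_len(g$n1 * g$n2))
    col0 <- col0 + g$n1 * g$n2
  }
  D <- Matrix::sparseMatrix(
    i = unlist(lapply(blocks, `[[`, "i")),
    j = unlist(lapply(blocks, `[[`, "j")),
    x = unlist(lapply(blocks, `[[`, "x")),
    dims = c(length(support), col0))
  D <- drop_small_entries(D, attenuation$sparsity_floor)
  structure(
    list(D = D, support = support, dims = grid$dims, fields = fields,
         attenuation = attenuation),
    class = "dose_influence")
}

# drop entries below `floor` * (column max); keeps the dgCMatrix class
drop_small_entries <- function(D, floor_rel) {
  D <- methods::as(methods::as(D, "CsparseMatrix"), "generalMatrix")
  if (floor_rel <= 0 || length(D@x) == 0L) return(D)
  nc <- ncol(D)
  p <- D@p
  counts <- diff(p)
  colid <- rep.int(seq_len(nc), counts)
  cmax <- vapply(seq_len(nc), function(c) {
    if (counts[c] == 0L) 0 else max(D@x[(p[c] + 1L):p[c + 1L]])
  }, numeric(1))
  keep <- D@x >= floor_rel * cmax[colid]
  Matrix::sparseMatrix(i = D@i[keep] + 1L, j = colid[keep], x = D@x[keep],
                       dims = dim(D))
}

#' @export
print.dose_influence <- function(x, ...) {
  cat("<dose_influence> ", nrow(x$D), " voxels x ", ncol(x$D), " beamlets (",
      length(x$fields), " fields), ", length(x$D@x), " nonzeros\n", sep = "")
  invisible(x)
}

#' Forward dose from beamlet weights
#'
#' @param influence a `dose_influence` from [assemble_influence()]
#' @param weights nonnegative numeric vector, one entry per beamlet column
#' @return 3-D dose array (Gy) on the influence grid (zeros off-support)
#' @export
dose_from_fluence <- function(influence, weights) {
  if (length(weights) != ncol(influence$D)) {
    stop("weight length ", length(weights), " != beamlet count ",
         ncol(influence$D))
  }
  if (any(weights < 0)) stop("beamlet weights must be nonnegative")
  d <- as.numeric(influence$D %*% weights)
  out <- array(0, dim = influence$dims)
  out[influence$support] <- d
  out
}

#' Dose of a fixed open field through a square or circular collimator
#'
#' Unit fluence weight on every beamlet whose isocenter-plane center falls
#' inside the aperture; equivalent to [dose_from_fluence()] with unit
#' weights on those beamlets, computed over the full grid.
#'
#' @param grid a [voxel_grid()]
#' @param geometry a [beam_geometry()]; its lattice is replaced by one just
#'   covering the aperture
#' @param attenuation an [attenuation_model()]
#' @param shape `"square"` or `"circle"`
#' @param size_mm square side or circle diameter, mm (0 gives zero dose)
#' @param materials optional material-id array
#' @return 3-D dose array (Gy)
#' @export
fixed_field_dose <- function(grid, geometry, attenuation, shape, size_mm,
                             materials = NULL) {
  shape <- match.arg(shape, c("square", "circle"))
  if (size_mm < 0) stop("aperture size must be >= 0")
  b <- geometry$beamlet_mm
  n <- floor(size_mm / b + 1e-9)
  if (n < 1) return(array(0, dim = grid$dims))
  x0 <- -(n - 1) / 2 * b
  centers <- x0 + (seq_len(n) - 1) * b
  ap <- outer(centers, centers, function(x, y) {
    if (shape == "square") rep(TRUE, length(x))
    else x^2 + y^2 <= (size_mm / 2)^2
  })
  if (shape == "square") ap <- matrix(TRUE, n, n)
  materials <- default_materials(grid, materials)
  dose <- cpp_fixed_field_dose(
    grid$density, grid$dims, grid$spacing, grid$origin,
    as.integer(materials), enh_vector(attenuation), as.logical(ap),
    geometry$source, geometry$isocenter, geometry$e1, geometry$e2,
    geometry$sid, n, n, b, x0, x0,
    attenuation$mu_water, attenuation$sigma_mm,
    attenuation$cutoff_sigma * attenuation$sigma_mm,
    attenuation$calibration)
  array(dose, dim = grid$dims)
}
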