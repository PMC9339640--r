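#' Fixed collimator shapes of the 3D baseline planner
#'
#' The five deliverable apertures: 40, 20 and 10 mm squares and 10 and 5 mm
#' circles, ordered by aperture area (the order in which the auto-placer
#' tries them).
#' @export
fixed_collimators <- function() {
  list(list(shape = "circle", size = 5),
       list(shape = "circle", size = 10),
       list(shape = "square", size = 10),
       list(shape = "square", size = 20),
       list(shape = "square", size = 40))
}

REGION_NAMES_7 <- c("head", "cervical_spine", "shoulders",
                    "dorsal_spine_spleen", "lumbar_spine", "femurs", "tibias")

#' Automatic region and beam placement for the 3D baseline plan
#'
#' Partitions the PTV cranio-caudal extent into contiguous slabs, one
#' parallel-opposed beam pair per slab. Each slab's length equals its chosen
#' collimator size so that abutting field edges coincide exactly at the slab
#' boundary planes (field matching); the collimator is the smallest fixed
#' shape that covers the slab's PTV cross-section. Slabs whose PTV is wider
#' (left-right) than 10 mm — the limb and shoulder girdle regions — receive
#' dorso-ventral beam pairs; the others (head and spine) lateral pairs,
#' so perpendicular-to-lateral beam intersections arise at those junctions.
#'
#' @param structures a [structure_set()] with `skeleton` and `spleen`
#' @param n_regions target number of regions (default 7, the canonical
#'   head / cervical / shoulders / dorsal+spleen / lumbar / femurs / tibias
#'   split; fewer emerge for small targets)
#' @param size_tol_mm slack (mm) allowed when matching a collimator size to
#'   the even-partition slab length
#' @return list of `region_beam_set` objects: `name`, `z_range`,
#'   `isocenter`, `collimator` (shape + size), `axis` (`"lateral"` or
#'   `"dorso_ventral"`), `norm_point` (world mm), `norm_index` (voxel),
#'   `weight` (NA until normalized)
#' @export
auto_place_regions <- function(structures, n_regions = 7L, size_tol_mm = 1.0) {
  grid <- structures$grid
  ptv <- ptv_mask(structures, 0)
  if (!any(ptv)) stop("empty PTV")
  pts <- mask_world_coords(grid, ptv)
  extent <- diff(range(pts[, 3]))
  # A full mouse target (head through tibias) gets the canonical 7-region
  # split; small or partial targets fall back to a generic greedy tiling.
  if (n_regions == 7L && extent > 60) {
    place_mouse_regions(grid, ptv, pts)
  } else {
    place_regions_greedy(grid, ptv, pts, n_regions, size_tol_mm)
  }
}

# canonical mouse template: slab lengths equal the collimator sizes so
# abutting field edges coincide exactly; head and spine slabs get lateral
# opposed pairs, the limb slabs (femurs, tibias) dorso-ventral pairs
place_mouse_regions <- function(grid, ptv, pts) {
  sizes <- c(20, 10, 10, 10, 10, 20, 20)
  axes <- c(rep("lateral", 5), rep("dorso_ventral", 2))
  zb <- min(pts[, 3]) - 1e-6 + cumsum(c(0, sizes))
  regions <- vector("list", 7L)
  for (i in 1:7) {
    reg <- make_region(grid, ptv, pts, zb[i], sizes[i],
                       list(shape = "square", size = sizes[i]), axes[i])
    if (is.null(reg)) stop("canonical slab ", i, " contains no target")
    w1 <- if (axes[i] == "dorso_ventral") reg$w1x else reg$w1y
    if (sizes[i] < w1) {
      stop("PTV cross-section too large for the ", sizes[i],
           " mm collimator in slab ", i, " (", REGION_NAMES_7[i], ")")
    }
    reg$name <- REGION_NAMES_7[i]
    regions[[i]] <- reg
  }
  regions
}

place_regions_greedy <- function(grid, ptv, pts, n_regions, size_tol_mm) {
  zmax <- max(pts[, 3])
  z_cur <- min(pts[, 3]) - 1e-6
  regions <- list()
  k <- 0L
  while (z_cur < zmax - 1e-9) {
    k <- k + 1L
    z_cur <- min(pts[pts[, 3] > z_cur, 3]) - 1e-6  # skip target gaps
    rem <- max(n_regions - length(regions), 1L)
    tentative <- (zmax - z_cur) / rem
    best <- NULL
    best_gap <- Inf
    for (cand in fixed_collimators()) {
      reg <- make_region(grid, ptv, pts, z_cur, cand$size, cand, NULL)
      if (is.null(reg)) next
      w1 <- if (reg$axis == "dorso_ventral") reg$w1x else reg$w1y
      covers <- if (cand$shape == "square") cand$size >= w1
                else cand$size >= sqrt(w1^2 + reg$wz^2)
      if (!covers) next
      if (rem == 1L && cand$size < zmax - z_cur - size_tol_mm) next
      gap <- abs(cand$size - tentative)
      if (gap < best_gap) { best <- reg; best_gap <- gap }
    }
    if (is.null(best)) {
      stop("PTV cross-section too large for the largest collimator in slab ", k)
    }
    regions[[k]] <- best
    z_cur <- best$z_range[2]
  }
  nms <- if (length(regions) == 7L) REGION_NAMES_7
         else paste0("region", seq_along(regions))
  for (i in seq_along(regions)) regions[[i]]$name <- nms[i]
  regions
}

# build one slab region; axis NULL means auto (dorso-ventral when the slab
# target is substantially wider left-right than 12 mm, i.e. bilateral limbs)
make_region <- function(grid, ptv, pts, z0, size, collimator, axis) {
  inwin <- pts[, 3] >= z0 & pts[, 3] <= z0 + size + 1e-9
  sub <- pts[inwin, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  sp <- grid$spacing
  w1x <- diff(range(sub[, 1])) + sp[1]
  w1y <- diff(range(sub[, 2])) + sp[2]
  wz <- diff(range(sub[, 3])) + sp[3]
  if (is.null(axis)) axis <- if (w1x > 12) "dorso_ventral" else "lateral"
  iso <- c(mean(range(sub[, 1])), mean(range(sub[, 2])), z0 + size / 2)
  norm <- nearest_mask_voxel(grid, ptv, colMeans(sub))
  structure(
    list(name = NA_character_, z_range = c(z0, z0 + size),
         isocenter = iso, collimator = collimator, axis = axis,
         norm_point = norm$world, norm_index = norm$index,
         weight = NA_real_, w1x = w1x, w1y = w1y, wz = wz),
    class = "region_beam_set")
}

# nearest mask voxel to a world point: returns its linear index and center
nearest_mask_voxel <- function(grid, mask, point) {
  co <- mask_world_coords(grid, mask)
  d2 <- (co[, 1] - point[1])^2 + (co[, 2] - point[2])^2 + (co[, 3] - point[3])^2
  j <- which.min(d2)
  list(index = which(mask)[j], world = co[j, ])
}

#' Compute the parallel-opposed 3D baseline plan
#'
#' For every region, two opposed fixed-collimator beams (lateral pairs at
#' gantry 90/270 degrees, dorso-ventral pairs at 0/180) are summed and the
#' region weight is set so the dose at the region's normalization point
#' equals the prescription. The total dose is the sum over regions; junction
#' hot spots (voxel clusters above 110% of prescription) are reported.
#'
#' @param phantom a `phantom` (or list with `grid`, `structures`,
#'   `materials`)
#' @param regions from [auto_place_regions()] (default: auto-placed)
#' @param prescription prescription dose, Gy
#' @param attenuation an [attenuation_model()]
#' @param junction_threshold hot-spot threshold, % of prescription
#' @return object of class `plan3d`: `dose`, `regions` (with weights),
#'   `junctions` (a [junction_report()]), `prescription`
#' @export
compute_3d_plan <- function(phantom, regions = NULL, prescription = 12,
                            attenuation = attenuation_model(),
                            junction_threshold = 110) {
  grid <- phantom$grid
  if (is.null(regions)) regions <- auto_place_regions(phantom$structures)
  stopifnot(length(regions) >= 1, prescription > 0)
  total <- array(0, dim = grid$dims)
  for (i in seq_along(regions)) {
    rg <- regions[[i]]
    angles <- if (rg$axis == "lateral") c(90, 270) else c(0, 180)
    pair <- array(0, dim = grid$dims)
    for (a in angles) {
      g <- beam_geometry(a, rg$isocenter, beamlet_mm = 1.0)
      pair <- pair + fixed_field_dose(grid, g, attenuation,
                                      rg$collimator$shape, rg$collimator$size,
                                      phantom$materials)
    }
    at_norm <- pair[rg$norm_index]
    if (at_norm <= 0) {
      stop("normalization point of region '", rg$name, "' receives zero dose")
    }
    regions[[i]]$weight <- prescription / at_norm
    total <- total + regions[[i]]$weight * pair
  }
  structure(
    list(dose = total, regions = regions, prescription = prescription,
         junctions = junction_report(total, prescription, junction_threshold)),
    class = "plan3d")
}

#' @export
print.plan3d <- function(x, ...) {
  cat("<plan3d> ", length(x$regions), " regions, prescription ",
      x$prescription, " Gy\n", sep = "")
  for (r in x$regions) {
    cat(sprintf("  %-20s %6s %2.0f mm  %-13s z [%5.1f, %5.1f] mm\n",
                r$name, r$collimator$shape, r$collimator$size, r$axis,
                r$z_range[1], r$z_range[2]))
  }
  cat("  junction clusters >", x$junctions$threshold, "%: ",
      nrow(x$junctions$clusters), "\n", sep = "")
  invisible(x)
}

#' Junction hot-spot report
#'
#' Connected components (26-connectivity) of voxels exceeding a threshold
#' percentage of the prescription.
#'
#' @param dose 3-D dose array (Gy)
#' @param prescription prescription dose, Gy
#' @param threshold percent of prescription, must exceed 100
#' @return object of class `junction_report`: `clusters` data frame with
#'   `id`, `size` (voxels), `peak_pct`; plus `threshold`
#' @export
junction_report <- function(dose, prescription, threshold = 110) {
  stopifnot(threshold > 100, prescription > 0)
  hot <- dose > threshold / 100 * prescription
  labels <- cpp_label_components(as.logical(hot), dim(dose))
  clusters <- if (any(hot)) {
    lab <- labels[labels > 0]
    val <- 100 * dose[labels > 0] / prescription
    sizes <- tabulate(lab)
    peaks <- vapply(split(val, lab), max, numeric(1))
    data.frame(id = seq_along(sizes), size = sizes, peak_pct = as.numeric(peaks))
  } else {
    data.frame(id = integer(), size = integer(), peak_pct = numeric())
  }
  structure(list(clusters = clusters, threshold = threshold),
            class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat("<junction_report> ", nrow(x$clusters), " clusters above ",
      x$threshold, "% of prescription\n", sep = "")
  if (nrow(x$clusters)) print(utils::head(x$clusters[order(-x$clusters$size), ], 10))
  invisible(x)
}
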