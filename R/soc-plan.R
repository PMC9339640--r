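#' Configuration for the SOC marrow-irradiation planner
#'
#' @param prescription prescription dose, Gy (default 12).
#' @param margin_mm PTV dilation margin (default 0: skeleton plus spleen).
#' @param lattice_margin_mm extra beamlet-lattice margin around the PTV
#'   projection, mm.
#' @param beamlet_mm beamlet size at the isocenter plane (default 1 mm).
#' @param sid source-to-isocenter distance, mm (default 305.4).
#' @param weights named list of penalty weights: `ptv_under`, `ptv_over`
#'   (applied above `ptv_over_frac` times the prescription) and per-OAR
#'   overdose weights (goal 0); `body` covers soft tissue outside PTV and
#'   OARs.
#' @param ptv_over_frac PTV max-dose goal as a fraction of prescription.
#' @param lambda_rel relative TV regularization strength.
#' @param max_iter,tol FISTA iteration cap and convergence tolerance.
#' @param decomp_tol,budget rectangle-decomposition relative L1 tolerance
#'   and per-field rectangle budget.
#' @param normalize `"ptv_median"` rescales the delivered plan so the PTV
#'   median dose equals the prescription; `"none"` keeps the optimizer
#'   scale.
#' @param attenuation an [attenuation_model()].
#' @return object of class `soc_config`
#' @export
soc_config <- function(prescription = 12, margin_mm = 0,
                       lattice_margin_mm = 3, beamlet_mm = 1.0, sid = 305.4,
                       weights = list(ptv_under = 100, ptv_over = 10,
                                      lungs = 10, kidneys = 10, liver = 5,
                                      heart = 5, bowel = 5, body = 2),
                       ptv_over_frac = 1.1, lambda_rel = 0.01,
                       max_iter = 400L, tol = 1e-6,
                       decomp_tol = 0.02, budget = 128L,
                       normalize = c("ptv_median", "none"),
                       attenuation = attenuation_model()) {
  stopifnot(prescription > 0, margin_mm >= 0, beamlet_mm > 0)
  structure(
    list(prescription = prescription, margin_mm = margin_mm,
         lattice_margin_mm = lattice_margin_mm, beamlet_mm = beamlet_mm,
         sid = sid, weights = weights, ptv_over_frac = ptv_over_frac,
         lambda_rel = lambda_rel, max_iter = as.integer(max_iter), tol = tol,
         decomp_tol = decomp_tol, budget = as.integer(budget),
         normalize = match.arg(normalize), attenuation = attenuation),
    class = "soc_config")
}

# world coordinates (n x 3) of the voxel centers of a mask
mask_world_coords <- function(grid, mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(grid$origin[1] + (idx[, 1] - 1) * grid$spacing[1],
        grid$origin[2] + (idx[, 2] - 1) * grid$spacing[2],
        grid$origin[3] + (idx[, 3] - 1) * grid$spacing[3])
}

mask_centroid <- function(grid, mask) colMeans(mask_world_coords(grid, mask))

#' Plan a seven-field SOC marrow irradiation
#'
#' Builds seven equally distributed coplanar fields around the PTV centroid,
#' assembles the sparse dose-influence matrix over body plus dilated PTV,
#' optimizes per-field fluence by FISTA with a TV (rectangle-promoting)
#' regularizer, decomposes each fluence map into weighted rectangular
#' apertures, and recomputes the dose actually delivered by the rectangles.
#'
#' @param phantom a `phantom` from [generate_phantom()], or any list with
#'   `grid`, `structures`, `materials`
#' @param config a [soc_config()]
#' @param keep_influence retain the influence matrix on the returned plan
#'   (large; default FALSE)
#' @return object of class `soc_plan`: `dose` (delivered, Gy), `dose_optimal`
#'   (pre-decomposition), `fluence` (the [optimize_fluence()] result),
#'   `delivered_maps`, `rectangles` (data frame with `field` column),
#'   `rect_counts`, `decomposition_gap` (per-field relative L1),
#'   `normalization`, `prescription`, `ptv` mask, `converged`
#' @export
plan_soc_tmi <- function(phantom, config = soc_config(), keep_influence = FALSE) {
  grid <- phantom$grid
  structures <- phantom$structures
  ptv <- ptv_mask(structures, config$margin_mm)
  if (!any(ptv)) stop("empty PTV")
  iso <- mask_centroid(grid, ptv)
  pts <- mask_world_coords(grid, ptv)

  mlat <- config$lattice_margin_mm
  b <- config$beamlet_mm
  z_rel <- pts[, 3] - iso[3]
  z_lo <- min(z_rel) - mlat
  n2 <- ceiling((max(z_rel) + mlat - z_lo) / b)

  geometries <- lapply(0:6, function(k) {
    ang <- k * 360 / 7
    th <- ang * pi / 180
    e1 <- c(cos(th), -sin(th), 0)
    p1 <- (pts[, 1] - iso[1]) * e1[1] + (pts[, 2] - iso[2]) * e1[2]
    lo <- min(p1) - mlat
    n1 <- ceiling((max(p1) + mlat - lo) / b)
    beam_geometry(ang, iso, sid = config$sid, n1 = n1, n2 = n2,
                  beamlet_mm = b, offset = c(lo + b / 2, z_lo + b / 2))
  })

  support <- get_mask(structures, "body") |
    dilate_mask(ptv, grid$spacing, mlat)
  influence <- assemble_influence(grid, geometries, config$attenuation,
                                  support, phantom$materials)

  terms <- soc_objective_terms(structures, ptv, config)
  objective <- objective_spec(terms, lambda_rel = config$lambda_rel,
                              max_iter = config$max_iter, tol = config$tol)
  fl <- optimize_fluence(influence, objective)

  decomp <- lapply(fl$maps, decompose_rectangles,
                   tol = config$decomp_tol, budget = config$budget)
  delivered_maps <- lapply(decomp, fluence_from_rectangles)
  xd <- unlist(lapply(delivered_maps, as.numeric))
  dose_del <- dose_from_fluence(influence, xd)
  dose_opt <- dose_from_fluence(influence, fl$x)

  scale <- 1
  if (config$normalize == "ptv_median") {
    med <- stats::median(dose_del[ptv])
    if (med <= 0) stop("delivered PTV median dose is zero; cannot normalize")
    scale <- config$prescription / med
    dose_del <- dose_del * scale
    dose_opt <- dose_opt * scale
    delivered_maps <- lapply(delivered_maps, function(m) m * scale)
    for (f in seq_along(decomp)) {
      decomp[[f]]$rectangles$weight <- decomp[[f]]$rectangles$weight * scale
    }
  }

  rectangles <- do.call(rbind, lapply(seq_along(decomp), function(f) {
    r <- decomp[[f]]$rectangles
    if (nrow(r)) cbind(field = f, r) else NULL
  }))

  structure(
    list(dose = dose_del, dose_optimal = dose_opt, fluence = fl,
         delivered_maps = delivered_maps, rectangles = rectangles,
         rect_counts = vapply(decomp, function(d) nrow(d$rectangles), integer(1)),
         decomposition_gap = vapply(decomp, `[[`, numeric(1), "achieved"),
         normalization = scale, prescription = config$prescription,
         isocenter = iso, angles = vapply(geometries, `[[`, numeric(1), "angle_deg"),
         ptv = ptv, converged = fl$converged, config = config,
         influence = if (keep_influence) influence),
    class = "soc_plan")
}

# objective terms for the SOC plan on a phantom structure set
soc_objective_terms <- function(structures, ptv, config) {
  w <- config$weights
  p <- config$prescription
  terms <- list(
    list(structure = "ptv", mask = ptv, type = "under", dose = p,
         weight = w$ptv_under),
    list(structure = "ptv", mask = ptv, type = "over",
         dose = p * config$ptv_over_frac, weight = w$ptv_over))
  oars <- intersect(c("lungs", "kidneys", "liver", "heart", "bowel"),
                    names(structures$masks))
  oar_union <- array(FALSE, dim = structures$grid$dims)
  for (s in oars) {
    m <- get_mask(structures, s) & !ptv
    oar_union <- oar_union | m
    terms[[length(terms) + 1L]] <-
      list(structure = s, mask = m, type = "over", dose = 0, weight = w[[s]])
  }
  rest <- get_mask(structures, "body") & !ptv & !oar_union
  terms[[length(terms) + 1L]] <-
    list(structure = "body", mask = rest, type = "over", dose = 0,
         weight = w$body)
  terms
}

#' @export
print.soc_plan <- function(x, ...) {
  cat("<soc_plan> 7 coplanar fields, prescription ", x$prescription, " Gy\n",
      "  rectangles per field: ", paste(x$rect_counts, collapse = ", "), "\n",
      "  decomposition relative L1 gap: ",
      paste(format(x$decomposition_gap, digits = 2), collapse = ", "), "\n",
      "  optimizer ", if (x$converged) "converged" else "hit iteration cap",
      " after ", x$fluence$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @export
summary.soc_plan <- function(object, ...) {
  p <- object$prescription
  cat("PTV median: ", format(100 * stats::median(object$dose[object$ptv]) / p,
                             digits = 4), "% of prescription\n", sep = "")
  cat("Max dose: ", format(100 * max(object$dose) / p, digits = 4),
      "% of prescription\n", sep = "")
  invisible(object)
}

#' @export
plot.soc_plan <- function(x, slice = NULL, ...) {
  d <- x$dose
  if (is.null(slice)) slice <- which.max(apply(d, 2, max))
  graphics::image(d[, slice, ], main = sprintf("soc_plan dose, coronal slice %d", slice),
                  xlab = "x", ylab = "z", useRaster = TRUE, ...)
  invisible(x)
}

#' Serialize a SOC plan to a JSON manifest plus a dose volume
#'
#' The manifest lists fields (angles, lattice shape) and rectangles as
#' `[field, r0, r1, c0, c1, weight]` with 0-based half-open row/column
#' intervals on the beamlet lattice.
#'
#' @param plan a `soc_plan`
#' @param dir output directory (created if needed)
#' @param grid the planning [voxel_grid()] (for dose-volume geometry)
#' @return `dir`, invisibly
#' @export
write_soc_plan <- function(plan, dir, grid) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- plan$rectangles
  manifest <- list(
    prescription_Gy = plan$prescription,
    isocenter_mm = plan$isocenter,
    angles_deg = plan$angles,
    rect_counts = plan$rect_counts,
    normalization = plan$normalization,
    rectangles = if (is.null(r)) list() else
      unname(lapply(seq_len(nrow(r)), function(k) {
        c(r$field[k], r$row0[k] - 1, r$row1[k], r$col0[k] - 1, r$col1[k],
          r$weight[k])
      })))
  jsonlite::write_json(manifest, file.path(dir, "soc_plan.json"),
                       auto_unbox = TRUE, digits = NA)
  write_volume(file.path(dir, "dose.mha"), plan$dose, grid = grid)
  invisible(dir)
}
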