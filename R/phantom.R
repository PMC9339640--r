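#' Analytic shape primitives
#'
#' Voxelize simple solids on a grid: a voxel belongs to the mask when its
#' center lies inside the shape (voxel-center-in-shape convention). These
#' primitives are the building blocks of the synthetic phantom and give
#' analytically known volumes for testing.
#'
#' @param grid a [voxel_grid()]
#' @param center,p0,p1 world points, mm
#' @param radius radius in mm
#' @param semi ellipsoid semi-axes in mm (length 3)
#' @return logical 3-D array
#' @name shape-primitives
NULL

#' @rdname shape-primitives
#' @export
mask_sphere <- function(grid, center, radius) {
  mask_ellipsoid(grid, center, rep(radius, 3))
}

#' @rdname shape-primitives
#' @export
mask_ellipsoid <- function(grid, center, semi) {
  stopifnot(length(center) == 3L, length(semi) == 3L, all(semi > 0))
  u <- ((grid_axis(grid, 1) - center[1]) / semi[1])^2
  v <- ((grid_axis(grid, 2) - center[2]) / semi[2])^2
  w <- ((grid_axis(grid, 3) - center[3]) / semi[3])^2
  outer(outer(u, v, "+"), w, "+") <= 1
}

#' @rdname shape-primitives
#' @export
mask_capsule <- function(grid, p0, p1, radius) {
  stopifnot(length(p0) == 3L, length(p1) == 3L, radius > 0)
  co <- grid_coordinate_arrays(grid)
  d <- p1 - p0
  dd <- sum(d * d)
  if (dd == 0) return(mask_sphere(grid, p0, radius))
  t <- ((co$x - p0[1]) * d[1] + (co$y - p0[2]) * d[2] + (co$z - p0[3]) * d[3]) / dd
  t <- pmin(pmax(t, 0), 1)
  (co$x - p0[1] - t * d[1])^2 + (co$y - p0[2] - t * d[2])^2 +
    (co$z - p0[3] - t * d[3])^2 <= radius^2
}

# elliptic cylinder along z with hard z range
mask_elliptic_cylinder <- function(grid, center_xy, semi_xy, z_range) {
  u <- ((grid_axis(grid, 1) - center_xy[1]) / semi_xy[1])^2
  v <- ((grid_axis(grid, 2) - center_xy[2]) / semi_xy[2])^2
  zs <- grid_axis(grid, 3)
  inz <- zs >= z_range[1] & zs <= z_range[2]
  r2 <- outer(u, v, "+") <= 1
  outer(r2, inz, "&")
}

PHANTOM_ORGANS <- c("spleen", "heart", "lungs", "kidneys", "liver", "bowel")

#' Configuration of the synthetic mouse phantom
#'
#' Describes a prone digital mouse: a soft-tissue body with a cranio-caudal
#' vertebral column near the dorsal surface, skull, shoulder girdle, pelvis,
#' femurs and tibias (the skeletal target), a spleen (co-target), and the
#' organs at risk. Lungs and kidneys are placed flush against the spine --
#' the anatomic adjacency that makes marrow-conformal planning hard. Organ
#' shapes are unions of analytic primitives so masks have testable volumes.
#'
#' @param spacing voxel spacing in mm (isotropic scalar or length-3).
#'   Default 0.5 mm, a desk-scale stand-in for a ~0.2 mm CBCT grid.
#' @param seed integer seed for the shape jitter.
#' @param jitter_mm per-organ random translation amplitude (uniform in
#'   `[-jitter_mm, jitter_mm]` per axis), emulating subject-to-subject
#'   contour variation. 0 disables jitter.
#' @param densities list with `soft`, `lung`, `bone` in g/cm^3.
#' @param include character vector of structures to generate besides `body`
#'   and `skeleton`; subset of `r toString(PHANTOM_ORGANS)`. Use
#'   `character(0)` with `skeleton = FALSE` for a body-only phantom.
#' @param skeleton include the skeletal structures (default TRUE).
#' @return object of class `phantom_config`
#' @export
phantom_config <- function(spacing = 0.5, seed = 1L, jitter_mm = 0.5,
                           densities = list(soft = 1.00, lung = 0.26, bone = 1.85),
                           include = PHANTOM_ORGANS, skeleton = TRUE) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(all(spacing > 0), jitter_mm >= 0)
  with(densities, stopifnot(soft > 0, lung > 0, bone > 0, lung < soft, soft < bone))
  bad <- setdiff(include, PHANTOM_ORGANS)
  if (length(bad)) stop("unknown phantom structures: ", paste(bad, collapse = ", "))
  structure(
    list(spacing = spacing, seed = as.integer(seed), jitter_mm = jitter_mm,
         densities = densities, include = include, skeleton = isTRUE(skeleton),
         extent = list(x = c(-14, 14), y = c(-11, 11), z = c(-2, 94))),
    class = "phantom_config")
}

# organ shape table: each entry is a list of primitives (type, params).
# Coordinates in mm; y+ is dorsal, z+ caudal. Chosen so that every shape
# lies strictly inside the body with >= 1 mm to spare (jitter-safe) and so
# that lungs and kidneys nominally overlap the spine (the overlap is carved
# away by the bone-first priority, leaving them flush against it).
phantom_shape_table <- function() {
  cap <- function(p0, p1, r) list(type = "capsule", p0 = p0, p1 = p1, r = r)
  ell <- function(c0, s) list(type = "ellipsoid", center = c0, semi = s)
  list(
    skeleton = list(
      skull = ell(c(0, -1.5, 8), c(4, 3.5, 5)),
      spine1 = cap(c(0, 4.8, 12), c(0, 4.2, 32), 1.5),
      spine2 = cap(c(0, 4.2, 32), c(0, 4.4, 52), 1.5),
      spine3 = cap(c(0, 4.4, 52), c(0, 4.2, 70), 1.5),
      shoulder_l = cap(c(-3, 4, 22), c(-9, 2, 26), 1.2),
      shoulder_r = cap(c(3, 4, 22), c(9, 2, 26), 1.2),
      pelvis_l = cap(c(-2, 4, 58), c(-5, 3, 64), 1.5),
      pelvis_r = cap(c(2, 4, 58), c(5, 3, 64), 1.5),
      femur_l = cap(c(-5, 3, 64), c(-7, 0, 74), 1.4),
      femur_r = cap(c(5, 3, 64), c(7, 0, 74), 1.4),
      tibia_l = cap(c(-7, 0, 74), c(-6, -2, 84), 1.2),
      tibia_r = cap(c(7, 0, 74), c(6, -2, 84), 1.2)
    ),
    spleen = list(ell(c(-6, 3, 40), c(2, 1.5, 6))),
    heart = list(ell(c(0, -2, 25), c(3, 3, 3.5))),
    lungs = list(ell(c(-4.2, 3.2, 27), c(4, 3.2, 6.5)),
                 ell(c(4.2, 3.2, 27), c(4, 3.2, 6.5))),
    kidneys = list(ell(c(-2.9, 3.8, 48), c(2.6, 2, 3.5)),
                   ell(c(2.9, 3.8, 48), c(2.6, 2, 3.5))),
    liver = list(ell(c(0, -1, 37), c(7, 4.5, 6))),
    bowel = list(ell(c(0, -1.5, 55), c(6.5, 4.5, 9)))
  )
}

phantom_body_mask <- function(grid) {
  torso <- mask_elliptic_cylinder(grid, c(0, 0), c(11, 8), c(8, 88))
  head <- mask_ellipsoid(grid, c(0, -1, 10), c(7, 6.5, 9))
  tail_cap <- mask_ellipsoid(grid, c(0, 0, 88), c(11, 8, 5))
  torso | head | tail_cap
}

render_shapes <- function(grid, shapes, shift = c(0, 0, 0)) {
  m <- array(FALSE, dim = grid$dims)
  for (s in shapes) {
    m <- m | switch(s$type,
      ellipsoid = mask_ellipsoid(grid, s$center + shift, s$semi),
      capsule = mask_capsule(grid, s$p0 + shift, s$p1 + shift, s$r),
      stop("unknown primitive type: ", s$type))
  }
  m
}

#' Generate the synthetic digital mouse phantom
#'
#' Deterministically renders the phantom described by a [phantom_config()]:
#' a density grid plus binary structure masks. Structures are made disjoint
#' by priority (skeleton first, then spleen, then the organs at risk); the
#' nominal lung/kidney overlap with the spine is carved away, leaving those
#' organs directly abutting the skeleton. Voxel density is the material
#' density of the innermost containing structure (bone > lung > soft
#' tissue); voxels outside the body have density 0.
#'
#' @param config a [phantom_config()]
#' @return object of class `phantom`: list with `grid` (a [voxel_grid()]
#'   carrying the density), `structures` (a [structure_set()] with masks
#'   `body`, `skeleton`, and the configured organs), `materials` (integer
#'   array: 0 soft tissue/air, 1 lung, 2 bone) and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  ext <- config$extent
  sp <- config$spacing
  dims <- c(floor(diff(ext$x) / sp[1]), floor(diff(ext$y) / sp[2]),
            floor(diff(ext$z) / sp[3])) + 1L
  grid <- voxel_grid(dims, sp, origin = c(ext$x[1], ext$y[1], ext$z[1]))

  body <- phantom_body_mask(grid)
  shapes <- phantom_shape_table()
  wanted <- c(if (config$skeleton) "skeleton", config$include)

  jitter <- local_seed(config$seed, {
    js <- lapply(wanted, function(nm) {
      if (config$jitter_mm > 0 && nm != "skeleton") {
        runif(3, -config$jitter_mm, config$jitter_mm)
      } else c(0, 0, 0)
    })
    names(js) <- wanted
    js
  })

  raw <- list()
  for (nm in wanted) {
    m <- render_shapes(grid, shapes[[nm]], jitter[[nm]])
    if (any(m & !body)) {
      stop("phantom structure '", nm, "' extends outside the body")
    }
    raw[[nm]] <- m
  }

  # carve by priority: skeleton > spleen > heart > lungs > kidneys > liver > bowel
  priority <- intersect(c("skeleton", "spleen", "heart", "lungs",
                          "kidneys", "liver", "bowel"), wanted)
  taken <- array(FALSE, dim = dims)
  masks <- list(body = body)
  for (nm in priority) {
    m <- raw[[nm]] & !taken
    taken <- taken | m
    masks[[nm]] <- m
  }

  density <- array(0, dim = dims)
  materials <- array(0L, dim = dims)
  density[body] <- config$densities$soft
  if (!is.null(masks$lungs)) {
    density[masks$lungs] <- config$densities$lung
    materials[masks$lungs] <- 1L
  }
  if (!is.null(masks$skeleton)) {
    density[masks$skeleton] <- config$densities$bone
    materials[masks$skeleton] <- 2L
  }
  grid$density <- density

  structure(
    list(grid = grid, structures = structure_set(grid, masks),
         materials = materials, config = config),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> seed", x$config$seed, "\n")
  print(x$grid)
  print(x$structures)
  invisible(x)
}

#' Planning target volume: skeleton plus spleen, optionally with margin
#'
#' @param structures a [structure_set()] containing `skeleton` and `spleen`
#' @param margin_mm isotropic dilation margin in mm (>= 0); 0 returns the
#'   exact union.
#' @return logical mask
#' @export
ptv_mask <- function(structures, margin_mm = 0) {
  stopifnot(margin_mm >= 0)
  m <- get_mask(structures, "skeleton") | get_mask(structures, "spleen")
  if (margin_mm == 0) return(m)
  dilate_mask(m, structures$grid$spacing, margin_mm)
}

#' Isotropic Euclidean dilation of a binary mask
#' @param mask logical 3-D array
#' @param spacing voxel spacing (mm, length 3)
#' @param margin_mm dilation radius in mm
#' @return logical array of the same dims
#' @export
dilate_mask <- function(mask, spacing, margin_mm) {
  if (margin_mm <= 0) return(mask)
  # center-to-center distances, compensated by a quarter voxel diagonal for
  # the sub-voxel extent of the digitized source region; keeps dilated
  # volumes close to the continuous Minkowski sum
  h <- sqrt(sum(spacing^2)) / 4
  r <- floor((margin_mm + h) / spacing) + 1
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d <- with(offs, sqrt((dx * spacing[1])^2 + (dy * spacing[2])^2 +
                         (dz * spacing[3])^2))
  offs <- offs[pmax(d - h, 0) <= margin_mm, , drop = FALSE]
  out <- array(FALSE, dim = dim(mask))
  d <- dim(mask)
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_mask(mask, c(offs$dx[i], offs$dy[i], offs$dz[i]))
  }
  out
}

# translate a logical array by integer voxel offsets, zero-filling
shift_mask <- function(mask, off) {
  d <- dim(mask)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= d[a]) return(array(FALSE, dim = d))
    if (o >= 0) { src[[a]] <- 1:(d[a] - o); dst[[a]] <- (1 + o):d[a] }
    else { src[[a]] <- (1 - o):d[a]; dst[[a]] <- 1:(d[a] + o) }
  }
  out <- array(FALSE, dim = d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Integral-dose reference region: body minus skeleton minus spleen
#'
#' The region over which whole-body integral dose is reported: the entire
#' body excluding the skeletal bones and the spleen.
#'
#' @param structures a [structure_set()] with `body`, `skeleton`, `spleen`
#' @return logical mask
#' @export
integral_dose_region <- function(structures) {
  get_mask(structures, "body") &
    !(get_mask(structures, "skeleton") | get_mask(structures, "spleen"))
}

# run expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
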