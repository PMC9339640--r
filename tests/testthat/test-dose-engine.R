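test_that("radiological path matches closed forms and is symmetric", {
  g <- water_grid()
  expect_equal(radiological_path(g, c(0, 10, 0), c(0, 20, 0)), 1.0)
  expect_equal(radiological_path(g, c(0, 20, 0), c(0, 10, 0)), 1.0)
  # degenerate and miss cases
  expect_equal(radiological_path(g, c(0, 10, 0), c(0, 10, 0)), 0)
  expect_equal(radiological_path(g, c(100, 0, 0), c(100, 10, 0)), 0)
})

test_that("radiological path agrees with the brute-force clipping oracle", {
  set.seed(11)
  g <- voxel_grid(c(8, 8, 8), c(1.3, 0.7, 1.1), origin = c(0, 0, 0),
                  density = array(runif(512, 0.2, 2), dim = c(8, 8, 8)))
  for (rep in 1:20) {
    p0 <- runif(3, -3, 12)
    p1 <- runif(3, -3, 12)
    a <- radiological_path(g, p0, p1)
    b <- radpath_bruteforce(g, p0, p1)
    expect_lt(abs(a - b), 1e-9 * max(b, 1e-3))
  }
})

test_that("central-axis depth dose follows exp(-mu d) with inverse square", {
  g <- water_grid()
  att <- attenuation_model()
  geom <- beam_geometry(0, isocenter = c(0, 30, 0))
  d <- beamlet_dose(g, geom, att, 1)
  ax <- d[11, , 11]
  ys <- grid_axis(g, 2)
  src_y <- geom$source[2]
  isf <- (geom$sid / (src_y - ys))^2
  depth <- max(ys) + 0.5 - ys           # water-equivalent depth in mm
  i1 <- which(abs(depth - 10.5) < 1e-9)
  i2 <- which(abs(depth - 30.5) < 1e-9)
  ratio <- (ax[i1] / isf[i1]) / (ax[i2] / isf[i2])
  expect_lt(abs(ratio / exp(att$mu_water * 2) - 1), 0.01)
  # monotone decrease with depth along the axis (after the entrance voxel)
  norm <- ax / isf
  expect_true(all(diff(norm[order(depth)]) <= 1e-12))
})

test_that("in vacuum the on-axis beamlet dose is pure inverse-square", {
  g <- voxel_grid(c(21, 61, 21), c(1, 1, 1), origin = c(-10, 0.5, -10),
                  density = 0)
  att <- attenuation_model()
  geom <- beam_geometry(0, isocenter = c(0, 30, 0))
  d <- beamlet_dose(g, geom, att, 1)
  ax <- d[11, , 11]
  ys <- grid_axis(g, 2)
  isf <- (geom$sid / (geom$source[2] - ys))^2
  expect_equal(ax / ax[1], isf / isf[1], tolerance = 1e-12)
})

test_that("bone receives the configured enhancement over soft tissue", {
  # two-material slab: bone voxel beside soft tissue at equal depth
  dims <- c(21, 41, 21)
  dens <- array(1, dim = dims)
  mats <- array(0L, dim = dims)
  # bone voxel at (9, 21, 11), soft at (13, 21, 11), both off-axis
  mats[9, 21, 11] <- 2L
  g <- voxel_grid(dims, c(1, 1, 1), origin = c(-10, 0.5, -10), density = dens)
  att <- attenuation_model()
  geom <- beam_geometry(0, isocenter = c(0, 20, 0), n1 = 21, n2 = 21,
                        beamlet_mm = 1)
  # open field so both voxels sit in identical lateral kernel surroundings
  d <- fixed_field_dose(g, geom, att, "square", 21, materials = mats)
  ratio <- d[9, 21, 11] / d[13, 21, 11]
  expect_equal(ratio, unname(att$enhancement["bone"]), tolerance = 1e-6)
  expect_gte(ratio, 2.5)
})

test_that("seven coplanar fields produce 7 x per-field beamlet columns", {
  g <- water_grid(dims = c(17, 17, 17), origin = c(-8, -8, -8))
  att <- attenuation_model()
  geoms <- seven_field_geometry(c(0, 0, 0), n1 = 5, n2 = 7)
  support <- array(TRUE, dim = g$dims)
  infl <- assemble_influence(g, geoms, att, support)
  expect_equal(ncol(infl$D), 7 * 5 * 7)
  expect_equal(length(infl$fields), 7)
  expect_true(all(infl$D@x >= 0))
  expect_error(assemble_influence(g, geoms, att, array(FALSE, dim = g$dims)),
               "empty")
})

test_that("influence columns superpose to the open-field forward dose", {
  g <- water_grid(dims = c(17, 31, 17), origin = c(-8, 0.5, -8))
  att <- attenuation_model()
  n <- 9
  geom <- beam_geometry(0, isocenter = c(0, 15, 0), n1 = n, n2 = n)
  support <- array(TRUE, dim = g$dims)
  infl <- assemble_influence(g, list(geom), att, support)
  d_sum <- dose_from_fluence(infl, rep(1, ncol(infl$D)))
  d_open <- fixed_field_dose(g, geom, att, "square", n)
  inside <- d_open > 0.2 * max(d_open)
  expect_lt(max(abs(d_sum[inside] - d_open[inside]) / d_open[inside]), 0.005)
})

test_that("a single-beamlet matrix equals that beamlet's dose column", {
  g <- water_grid(dims = c(17, 31, 17), origin = c(-8, 0.5, -8))
  att <- attenuation_model()
  geom <- beam_geometry(0, isocenter = c(0, 15, 0), n1 = 1, n2 = 1)
  infl <- assemble_influence(g, list(geom), att, array(TRUE, dim = g$dims))
  col <- dose_from_fluence(infl, 1)
  direct <- beamlet_dose(g, geom, att, 1)
  # influence applies the sparsity floor; agreement on retained entries
  nz <- col > 0
  expect_lt(max(abs(col[nz] - direct[nz])), 1e-12)
  expect_error(beamlet_dose(g, geom, att, 2), "out of range")
})

test_that("dose_from_fluence is linear, nonnegative, and validated", {
  g <- water_grid(dims = c(17, 31, 17), origin = c(-8, 0.5, -8))
  att <- attenuation_model()
  geom <- beam_geometry(0, isocenter = c(0, 15, 0), n1 = 4, n2 = 4)
  infl <- assemble_influence(g, list(geom), att, array(TRUE, dim = g$dims))
  w <- runif(16)
  expect_equal(dose_from_fluence(infl, 0 * w), array(0, dim = g$dims))
  expect_equal(dose_from_fluence(infl, 2 * w),
               2 * dose_from_fluence(infl, w), tolerance = 1e-14)
  # unit weights match the column-sum oracle
  expect_equal(dose_from_fluence(infl, rep(1, 16))[infl$support],
               as.numeric(Matrix::rowSums(infl$D)), tolerance = 1e-14)
  expect_error(dose_from_fluence(infl, rep(-1, 16)), "nonnegative")
  expect_error(dose_from_fluence(infl, rep(1, 5)), "length")
})

test_that("aperture monotonicity: circle dose never exceeds square dose", {
  g <- water_grid(dims = c(17, 31, 17), origin = c(-8, 0.5, -8))
  att <- attenuation_model()
  geom <- beam_geometry(0, isocenter = c(0, 15, 0))
  dc <- fixed_field_dose(g, geom, att, "circle", 5)
  ds <- fixed_field_dose(g, geom, att, "square", 5)
  expect_true(all(dc <= ds + 1e-14))
  expect_equal(fixed_field_dose(g, geom, att, "square", 0),
               array(0, dim = g$dims))
  expect_error(fixed_field_dose(g, geom, att, "hexagon", 5))
})

test_that("densifying an upstream voxel cannot increase the total dose", {
  dims <- c(9, 31, 9)
  base <- array(1, dim = dims)
  g1 <- voxel_grid(dims, c(1, 1, 1), origin = c(-4, 0.5, -4), density = base)
  dense <- base
  dense[5, 25, 5] <- 2   # upstream of the target (source sits at +y)
  g2 <- voxel_grid(dims, c(1, 1, 1), origin = c(-4, 0.5, -4), density = dense)
  att <- attenuation_model()
  geom <- beam_geometry(0, isocenter = c(0, 15, 0))
  d1 <- beamlet_dose(g1, geom, att, 1)
  d2 <- beamlet_dose(g2, geom, att, 1)
  expect_lt(sum(d2), sum(d1))
  # downstream voxels specifically receive less
  expect_true(all(d2[5, 1:24, 5] <= d1[5, 1:24, 5] + 1e-15))
})
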