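# a plain-water phantom-like object with a small central target
water_phantom <- function(dims = c(31, 31, 41), spacing = c(1, 1, 1),
                          origin = NULL, target_radius = 3) {
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  g <- voxel_grid(dims, spacing, origin, density = 1)
  sk <- mask_sphere(g, c(0, 0, 0), target_radius)
  body <- array(TRUE, dim = dims)
  ss <- structure_set(g, list(body = body, skeleton = sk,
                              spleen = array(FALSE, dim = dims)))
  list(grid = g, structures = ss, materials = NULL)
}

test_that("a small spherical target yields one region with the 10 mm square", {
  ph <- water_phantom(target_radius = 4)
  regions <- auto_place_regions(ph$structures)
  expect_equal(length(regions), 1)
  expect_equal(regions[[1]]$collimator$shape, "square")
  expect_equal(regions[[1]]$collimator$size, 10)
})

test_that("the default phantom is split into exactly seven matched regions", {
  ph <- generate_phantom(phantom_config(spacing = 1.0, seed = 2))
  regions <- auto_place_regions(ph$structures)
  expect_equal(length(regions), 7)
  # abutting field edges coincide exactly at the slab boundaries
  for (i in 1:6) {
    expect_lt(abs(regions[[i]]$z_range[2] - regions[[i + 1]]$z_range[1]), 1e-9)
  }
  # limb regions get the perpendicular (dorso-ventral) beam axis
  axes <- vapply(regions, `[[`, character(1), "axis")
  expect_true(all(axes[1:5] == "lateral"))
  expect_true(all(axes[6:7] == "dorso_ventral"))
})

test_that("region normalization delivers the prescription at the norm point", {
  ph <- water_phantom()
  ctr <- nearest <- which(get_mask(ph$structures, "skeleton"))
  center_idx <- ctr[which.min(abs(ctr - (prod(ph$grid$dims) + 1) / 2))]
  region <- structure(
    list(name = "mid", z_range = c(-20, 20), isocenter = c(0, 0, 0),
         collimator = list(shape = "square", size = 40), axis = "lateral",
         norm_point = c(0, 0, 0), norm_index = center_idx, weight = NA_real_),
    class = "region_beam_set")
  plan <- compute_3d_plan(ph, regions = list(region), prescription = 2)
  expect_equal(plan$dose[center_idx], 2, tolerance = 1e-3)
  expect_equal(length(plan$regions), 1)
  expect_true(is.finite(plan$regions[[1]]$weight))
})

test_that("matched coplanar opposed beams keep the junction near prescription", {
  dims <- c(21, 21, 40)
  g <- voxel_grid(dims, c(1, 1, 1), origin = c(-10, -10, 0.5), density = 1)
  body <- array(TRUE, dim = dims)
  ss <- structure_set(g, list(body = body,
                              skeleton = mask_sphere(g, c(0, 0, 20), 2),
                              spleen = array(FALSE, dim = dims)))
  ph <- list(grid = g, structures = ss, materials = NULL)
  mk <- function(z0, z1, normz) {
    ni <- which(abs(grid_axis(g, 3) - normz) < 0.6)[1]
    idx <- (11 - 1) + dims[1] * (11 - 1) + dims[1] * dims[2] * (ni - 1) + 1
    structure(
      list(name = paste0("r", z0), z_range = c(z0, z1),
           isocenter = c(0, 0, (z0 + z1) / 2),
           collimator = list(shape = "square", size = z1 - z0),
           axis = "lateral", norm_point = c(0, 0, normz), norm_index = idx,
           weight = NA_real_),
      class = "region_beam_set")
  }
  plan <- compute_3d_plan(ph, regions = list(mk(0.5, 20.5, 10.5),
                                             mk(20.5, 39.5, 30.5)),
                          prescription = 2)
  # dose along the central axis near the matched edge stays in [90%, 110%]
  line <- plan$dose[11, 11, 19:22] / 2 * 100
  expect_true(all(line >= 90 & line <= 110))
})

test_that("perpendicular limb beams create junction hot spots on the phantom", {
  ph <- generate_phantom(phantom_config(spacing = 1.0, seed = 2))
  plan <- compute_3d_plan(ph)
  expect_gt(nrow(plan$junctions$clusters), 0)
})

test_that("junction_report identifies constructed clusters exactly", {
  d <- array(1.0, dim = c(10, 10, 10))
  expect_equal(nrow(junction_report(d, 1, 110)$clusters), 0)
  d[4, 5, 6] <- 1.5
  rep1 <- junction_report(d, 1, 110)
  expect_equal(rep1$clusters$size, 1)
  expect_equal(rep1$clusters$peak_pct, 150)
  # two orthogonal 60% slabs: their intersection reaches 120%
  d2 <- array(0, dim = c(12, 12, 12))
  d2[4:6, , ] <- d2[4:6, , ] + 0.6
  d2[, 7:9, ] <- d2[, 7:9, ] + 0.6
  rep2 <- junction_report(d2, 1, 110)
  expect_equal(nrow(rep2$clusters), 1)
  expect_equal(rep2$clusters$size, 3 * 3 * 12)
  expect_equal(rep2$clusters$peak_pct, 120)
  expect_error(junction_report(d2, 1, 90), "threshold")
})
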