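test_that("body-only phantom is uniform soft tissue inside a single mask", {
  cfg <- phantom_config(spacing = 1.0, seed = 1, include = character(0),
                        skeleton = FALSE)
  ph <- generate_phantom(cfg)
  expect_named(ph$structures$masks, "body")
  body <- get_mask(ph$structures, "body")
  expect_true(all(ph$grid$density[body] == cfg$densities$soft))
  expect_true(all(ph$grid$density[!body] == 0))
})

test_that("phantom generation is deterministic for a fixed config and seed", {
  a <- generate_phantom(phantom_config(spacing = 1.0, seed = 7))
  b <- generate_phantom(phantom_config(spacing = 1.0, seed = 7))
  expect_identical(a$grid$density, b$grid$density)
  expect_identical(a$structures$masks, b$structures$masks)
  c <- generate_phantom(phantom_config(spacing = 1.0, seed = 8))
  expect_false(identical(a$structures$masks$kidneys, c$structures$masks$kidneys))
})

test_that("voxelized sphere volume matches the analytic value within 5%", {
  g <- voxel_grid(c(24, 24, 24), rep(0.5, 3), origin = c(-5.75, -5.75, -5.75))
  m <- mask_sphere(g, c(0, 0, 0), 4)
  analytic <- 4 / 3 * pi * 4^3 / voxel_volume(g)
  expect_lt(abs(sum(m) - analytic) / analytic, 0.05)
})

test_that("phantom masks respect the structural invariants", {
  ph <- generate_phantom(phantom_config(spacing = 0.5, seed = 3))
  ms <- ph$structures$masks
  body <- ms$body
  for (nm in setdiff(names(ms), "body")) {
    expect_true(all(body[ms[[nm]]]), info = nm)       # contained in body
  }
  expect_equal(sum(ms$lungs & ms$kidneys), 0)
  target <- ms$skeleton | ms$spleen
  for (nm in c("lungs", "kidneys", "liver", "heart", "bowel")) {
    expect_equal(sum(target & ms[[nm]]), 0, info = nm)
  }
  # density equals the material of the innermost structure
  expect_true(all(ph$grid$density[ms$skeleton] == 1.85))
  expect_true(all(ph$grid$density[ms$lungs] == 0.26))
  expect_true(all(ph$grid$density[ms$kidneys] == 1.00))
})

test_that("kidneys and lungs abut the skeleton (within 1 mm)", {
  for (seed in 1:5) {
    ph <- generate_phantom(phantom_config(spacing = 1.0, seed = seed))
    near <- dilate_mask(get_mask(ph$structures, "skeleton"),
                        ph$grid$spacing, 1.0)
    expect_gt(sum(near & get_mask(ph$structures, "kidneys")), 0)
    expect_gt(sum(near & get_mask(ph$structures, "lungs")), 0)
  }
})

test_that("an organ jittered outside the body raises a named error", {
  cfg <- phantom_config(spacing = 1.0, seed = 104, jitter_mm = 6)
  expect_error(generate_phantom(cfg), "outside the body")
})

test_that("ptv_mask honors the margin contract", {
  ph <- generate_phantom(phantom_config(spacing = 1.0, seed = 2))
  st <- ph$structures
  base <- ptv_mask(st, 0)
  expect_identical(base, get_mask(st, "skeleton") | get_mask(st, "spleen"))
  grown <- ptv_mask(st, 1.0)
  expect_true(all(grown[base]))
  expect_gt(sum(grown), sum(base))
  # missing mask errors
  st2 <- structure_set(ph$grid, list(body = get_mask(st, "body"),
                                     skeleton = get_mask(st, "skeleton")))
  expect_error(ptv_mask(st2, 0), "spleen")
})

test_that("dilated sphere volume matches the analytic dilated volume", {
  g <- voxel_grid(c(28, 28, 28), rep(0.5, 3), origin = c(-6.75, -6.75, -6.75))
  sph <- mask_sphere(g, c(0, 0, 0), 4)
  dil <- dilate_mask(sph, g$spacing, 1.0)
  analytic <- 4 / 3 * pi * 5^3 / voxel_volume(g)
  expect_lt(abs(sum(dil) - analytic) / analytic, 0.05)
})

test_that("integral-dose region is exact set arithmetic on the masks", {
  ph <- generate_phantom(phantom_config(spacing = 1.0, seed = 2))
  st <- ph$structures
  reg <- integral_dose_region(st)
  target <- get_mask(st, "skeleton") | get_mask(st, "spleen")
  expect_identical(reg, get_mask(st, "body") & !target)
  expect_equal(sum(reg), sum(get_mask(st, "body")) - sum(target))
  # degenerate cases
  g <- ph$grid
  empty <- array(FALSE, dim = g$dims)
  body <- get_mask(st, "body")
  s1 <- structure_set(g, list(body = body, skeleton = empty, spleen = empty))
  expect_identical(integral_dose_region(s1), body)
  s2 <- structure_set(g, list(body = body, skeleton = body, spleen = empty))
  expect_equal(sum(integral_dose_region(s2)), 0)
})

test_that("mask set-algebra identities hold exactly on a small grid", {
  g <- voxel_grid(c(16, 16, 16), rep(1, 3), origin = c(-7.5, -7.5, -7.5))
  a <- mask_sphere(g, c(-2, 0, 0), 4)
  b <- mask_sphere(g, c(2, 1, 1), 3)
  expect_identical(a & !b, a & !(a & b))
  expect_equal(sum(a | b), sum(a) + sum(b) - sum(a & b))
  brute <- array(FALSE, dim = g$dims)
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    brute[i, j, k] <- a[i, j, k] || b[i, j, k]
  }
  expect_identical(a | b, brute)
})
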