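test_that("cumulative DVH handles step-function cases exactly", {
  d <- array(2, dim = c(5, 5, 4))
  m <- array(TRUE, dim = dim(d))
  curve <- compute_dvh(d, m, bin_width = 0.5)
  expect_equal(curve$volume_fraction[curve$edges <= 2],
               rep(1, sum(curve$edges <= 2)))
  expect_equal(curve$volume_fraction[curve$edges > 2],
               rep(0, sum(curve$edges > 2)))
  # half at 1 Gy, half at 3 Gy: V(2) = 0.5 exactly
  d2 <- array(c(rep(1, 50), rep(3, 50)), dim = c(10, 10, 1))
  c2 <- compute_dvh(d2, array(TRUE, dim = dim(d2)), bin_width = 1)
  expect_equal(c2$volume_fraction[c2$edges == 2], 0.5)
  expect_error(compute_dvh(d, array(FALSE, dim = dim(d))), "empty")
})

test_that("DVH agrees with a direct sort-and-count oracle at every edge", {
  set.seed(41)
  d <- array(runif(100, 0, 10), dim = c(10, 10, 1))
  m <- array(TRUE, dim = dim(d))
  curve <- compute_dvh(d, m, bin_width = 0.25)
  v <- sort(as.numeric(d))
  for (i in seq_along(curve$edges)) {
    expect_equal(curve$volume_fraction[i], sum(v >= curve$edges[i]) / 100)
  }
  # V(0) = 1, nonincreasing, vanishing above the maximum
  expect_equal(curve$volume_fraction[1], 1)
  expect_true(all(diff(curve$volume_fraction) <= 0))
  expect_equal(curve$volume_fraction[length(curve$edges)], 0)
})

test_that("median and integral dose percentages match closed forms", {
  m <- array(TRUE, dim = c(3, 1, 1))
  expect_equal(median_dose_percent(array(6, dim = c(3, 1, 1)), m, 12), 50)
  expect_equal(median_dose_percent(array(c(1, 2, 3), dim = c(3, 1, 1)), m, 12),
               100 * 2 / 12)
  expect_equal(integral_dose_percent(array(12, dim = c(3, 1, 1)), m, 12), 100)
  expect_equal(integral_dose_percent(array(0, dim = c(3, 1, 1)), m, 12), 0)
  m2 <- array(TRUE, dim = c(2, 1, 1))
  expect_equal(integral_dose_percent(array(c(0, 12), dim = c(2, 1, 1)), m2, 12), 50)
  expect_error(median_dose_percent(array(1, dim = c(2, 1, 1)),
                                   array(FALSE, dim = c(2, 1, 1)), 12), "empty")
})

test_that("median matches the sort-based percentile oracle at scale", {
  set.seed(43)
  d <- array(runif(1e4, 0, 20), dim = c(100, 100, 1))
  m <- array(TRUE, dim = dim(d))
  v <- sort(as.numeric(d))
  oracle <- (v[5000] + v[5001]) / 2
  expect_equal(median_dose_percent(d, m, 12), 100 * oracle / 12,
               tolerance = 1e-12)
})

test_that("D50 from the DVH curve agrees with the direct median within one bin", {
  set.seed(45)
  d <- array(rexp(4000, 1 / 5), dim = c(20, 20, 10))
  m <- array(runif(4000) < 0.6, dim = dim(d))
  bw <- 0.2
  curve <- compute_dvh(d, m, bin_width = bw)
  direct <- median(d[m])
  expect_lt(abs(dvh_d50(curve) - direct), bw + 1e-12)
})

test_that("averaged DVH is the pointwise mean and stays monotone", {
  set.seed(47)
  mk <- function() {
    d <- array(runif(125, 0, 8), dim = c(5, 5, 5))
    compute_dvh(d, array(TRUE, dim = dim(d)), bin_width = 0.5, max_dose = 8)
  }
  curves <- replicate(6, mk(), simplify = FALSE)
  avg <- average_dvh(curves)
  expect_equal(avg$volume_fraction,
               rowMeans(sapply(curves, `[[`, "volume_fraction")))
  expect_true(all(diff(avg$volume_fraction) <= 0))
  # identical curves average to themselves
  same <- average_dvh(list(curves[[1]], curves[[1]]))
  expect_equal(same$volume_fraction, curves[[1]]$volume_fraction)
  # two step functions give the midpoint plateau
  u1 <- compute_dvh(array(2, dim = c(2, 2, 1)), array(TRUE, dim = c(2, 2, 1)),
                    bin_width = 1, max_dose = 6)
  u2 <- compute_dvh(array(5, dim = c(2, 2, 1)), array(TRUE, dim = c(2, 2, 1)),
                    bin_width = 1, max_dose = 6)
  mid <- average_dvh(list(u1, u2))
  expect_equal(mid$volume_fraction[mid$edges == 4], 0.5)
  # mismatched bins are rejected
  u3 <- compute_dvh(array(2, dim = c(2, 2, 1)), array(TRUE, dim = c(2, 2, 1)),
                    bin_width = 0.5, max_dose = 6)
  expect_error(average_dvh(list(u1, u3)), "mismatched")
})
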