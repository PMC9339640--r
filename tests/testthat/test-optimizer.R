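test_that("1-D TV prox matches the ADMM oracle on random cases", {
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(1:30, 1)
    y <- rnorm(n, sd = sample(c(0.2, 1, 5), 1))
    lam <- runif(1, 0, 2)
    expect_equal(prox_tv1d(y, lam), tv1d_admm(y, lam), tolerance = 1e-8)
  }
  # trivial edges
  expect_equal(prox_tv1d(3, 10), 3)
  expect_equal(prox_tv1d(c(1, 5), 0), c(1, 5))
})

test_that("row/column TV prox honors its limit and identity contracts", {
  m <- matrix(2.5, 4, 6)
  expect_equal(prox_tv_row_col(m, 1), m)          # constant map unchanged
  set.seed(3)
  r <- matrix(runif(24), 4, 6)
  expect_equal(prox_tv_row_col(r, 0), r)          # step -> 0 is the identity
  # a 1 x 5 map reduces to the exact 1-D prox
  y <- c(0.2, 3, 0.1, 2, 2.1)
  expect_equal(as.numeric(prox_tv_row_col(matrix(y, 1, 5), 0.4)),
               pmax(tv1d_admm(y, 0.4), 0), tolerance = 1e-8)
  # clamped at zero
  expect_true(all(prox_tv_row_col(matrix(rnorm(24), 4, 6), 0.3) >= 0))
})

test_that("lambda = 0 identity design recovers the target exactly", {
  infl <- toy_influence(diag(3), 3, 1)
  tgt <- c(1, 2, 3)
  terms <- lapply(1:3, function(i) {
    list(structure = paste0("v", i), rows = i, type = "under",
         dose = tgt[i], weight = 1)
  })
  terms <- c(terms, lapply(1:3, function(i) {
    list(structure = paste0("v", i), rows = i, type = "over",
         dose = tgt[i], weight = 1)
  }))
  fl <- optimize_fluence(infl, objective_spec(terms, lambda = 0,
                                              max_iter = 3000, tol = 1e-12))
  expect_equal(fl$x, tgt, tolerance = 1e-6)
  expect_true(fl$converged)
})

test_that("FISTA matches a long-run proximal-gradient oracle on tiny problems", {
  set.seed(5)
  for (case in 1:2) {
    M <- matrix(abs(rnorm(12 * 9)), 12, 9) * 0.6
    terms <- list(
      list(structure = "ptv", rows = 1:6, type = "under", dose = 2, weight = 10),
      list(structure = "ptv", rows = 1:6, type = "over", dose = 2.2, weight = 2),
      list(structure = "oar", rows = 7:12, type = "over", dose = 0, weight = 1))
    lambda <- c(0, 0.02)[case]
    infl <- toy_influence(M, 3, 3)
    fl <- optimize_fluence(infl, objective_spec(terms, lambda = lambda,
                                                max_iter = 5000, tol = 1e-12))
    x_oracle <- toy_pg_oracle(M, terms, lambda, 3, 3, iters = 20000)
    f_fista <- toy_objective_value(M, fl$x, terms, lambda, 3, 3)
    f_oracle <- toy_objective_value(M, x_oracle, terms, lambda, 3, 3)
    expect_lt(abs(f_fista - f_oracle) / max(abs(f_oracle), 1e-12), 1e-6)
  }
})

test_that("objective trace is nonincreasing on every test problem", {
  set.seed(9)
  for (rep in 1:5) {
    M <- matrix(abs(rnorm(10 * 6)), 10, 6)
    terms <- list(
      list(structure = "ptv", rows = 1:5, type = "under", dose = 1, weight = 5),
      list(structure = "oar", rows = 6:10, type = "over", dose = 0, weight = 1))
    infl <- toy_influence(M, 3, 2)
    fl <- optimize_fluence(infl, objective_spec(terms, lambda = 0.05,
                                                max_iter = 300))
    expect_true(all(diff(fl$trace) <= 1e-9 * max(1, abs(fl$trace[1]))))
  }
})

test_that("stronger TV flattens the fluence into fewer distinct levels", {
  set.seed(13)
  tgt <- round(runif(12, 0.5, 5), 2)
  terms <- c(
    lapply(1:12, function(i) list(structure = "v", rows = i, type = "under",
                                  dose = tgt[i], weight = 2)),
    lapply(1:12, function(i) list(structure = "v", rows = i, type = "over",
                                  dose = tgt[i], weight = 2)))
  count_levels <- function(x, tol = 1e-3) {
    s <- sort(x)
    1 + sum(diff(s) > tol * max(max(s), 1e-9))
  }
  levels_at <- function(lambda) {
    infl <- toy_influence(diag(12), 4, 3)
    fl <- optimize_fluence(infl, objective_spec(terms, lambda = lambda,
                                                max_iter = 6000, tol = 1e-12))
    count_levels(fl$x)
  }
  lv <- vapply(c(0, 0.05, 0.2, 1, 5, 50), levels_at, numeric(1))
  expect_true(all(diff(lv) <= 0))
})
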