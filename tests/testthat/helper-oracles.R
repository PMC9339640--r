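# Independent oracles and small constructors shared across tests.

# exact 1-D TV prox via ADMM on the difference operator (independent of the
# direct algorithm under test)
tv1d_admm <- function(y, lam, iters = 4000, rho = 2) {
  n <- length(y)
  if (n == 1 || lam == 0) return(y)
  D <- diff(diag(n))
  R <- chol(diag(n) + rho * crossprod(D))
  x <- y
  z <- as.numeric(D %*% x)
  u <- numeric(n - 1)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  for (i in seq_len(iters)) {
    x <- backsolve(R, forwardsolve(t(R), y + rho * crossprod(D, z - u)))
    Dx <- as.numeric(D %*% x)
    z <- soft(Dx + u, lam / rho)
    u <- u + Dx - z
  }
  as.numeric(x)
}

# brute-force radiological path: clip the segment against every voxel box
radpath_bruteforce <- function(grid, p0, p1) {
  d <- p1 - p0
  L <- sqrt(sum(d^2))
  if (L == 0) return(0)
  total <- 0
  for (i in seq_len(grid$dims[1])) for (j in seq_len(grid$dims[2]))
    for (k in seq_len(grid$dims[3])) {
      lo <- grid$origin + (c(i, j, k) - 1.5) * grid$spacing
      hi <- lo + grid$spacing
      t0 <- 0; t1 <- 1; ok <- TRUE
      for (a in 1:3) {
        if (d[a] == 0) {
          if (p0[a] <= lo[a] || p0[a] >= hi[a]) { ok <- FALSE; break }
        } else {
          ta <- (lo[a] - p0[a]) / d[a]; tb <- (hi[a] - p0[a]) / d[a]
          if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
          t0 <- max(t0, ta); t1 <- min(t1, tb)
        }
      }
      if (ok && t1 > t0) {
        total <- total + grid$density[i, j, k] * (t1 - t0) * L
      }
    }
  total * 0.1
}

# wrap a plain matrix as a dose_influence object (toy optimizer problems)
toy_influence <- function(M, n1, n2) {
  D <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  structure(
    list(D = D, support = seq_len(nrow(M)), dims = c(nrow(M), 1L, 1L),
         fields = list(list(geometry = NULL, n1 = as.integer(n1),
                            n2 = as.integer(n2), cols = seq_len(ncol(M)))),
         attenuation = NULL),
    class = "dose_influence")
}

# independent objective evaluation for toy problems (matches the model the
# optimizer is documented to minimize)
toy_objective_value <- function(M, x, terms, lambda, n1, n2) {
  d <- as.numeric(M %*% x)
  s <- 0
  for (t in terms) {
    r <- if (t$type == "under") pmax(t$dose - d[t$rows], 0)
         else pmax(d[t$rows] - t$dose, 0)
    s <- s + t$weight / length(t$rows) * sum(r^2)
  }
  map <- matrix(x, n1, n2)
  tv <- 0
  if (n1 > 1) tv <- tv + sum(abs(diff(map)))
  if (n2 > 1) tv <- tv + sum(abs(diff(t(map))))
  s + lambda * tv
}

# long-run unaccelerated projected/proximal gradient oracle with a
# conservative fixed step. The TV proximal subroutine is shared with the
# implementation but is itself validated against the independent ADMM
# oracle above; what this long run checks independently is the FISTA
# iteration and its convergence.
toy_pg_oracle <- function(M, terms, lambda, n1, n2, iters = 30000) {
  x <- numeric(ncol(M))
  wmax <- sum(vapply(terms, function(t) 2 * t$weight / length(t$rows),
                     numeric(1)))
  L <- wmax * norm(M, "2")^2
  step <- 1 / (L * 1.5)
  for (it in seq_len(iters)) {
    d <- as.numeric(M %*% x)
    g <- numeric(nrow(M))
    for (t in terms) {
      if (t$type == "under") {
        g[t$rows] <- g[t$rows] - 2 * t$weight / length(t$rows) *
          pmax(t$dose - d[t$rows], 0)
      } else {
        g[t$rows] <- g[t$rows] + 2 * t$weight / length(t$rows) *
          pmax(d[t$rows] - t$dose, 0)
      }
    }
    z <- x - step * as.numeric(crossprod(M, g))
    map <- prox_tv_row_col(matrix(z, n1, n2), step * lambda)
    x <- as.numeric(map)
  }
  x
}

# uniform water grid centered on the origin-ish, used by engine tests
water_grid <- function(dims = c(21, 61, 21), spacing = c(1, 1, 1),
                       origin = c(-10, 0.5, -10), density = 1) {
  voxel_grid(dims, spacing, origin, density)
}

# cached default cohort run (shared between the workflow tests and the
# comparative-dosimetry acceptance check)
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.cohort_cache$res)) {
    .cohort_cache$res <- run_pipeline(run_config(cohort = 5, master_seed = 1),
                                      verbose = FALSE)
  }
  .cohort_cache$res
}
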