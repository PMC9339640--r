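#' 1-D total-variation proximal operator
#'
#' Solves `argmin_x 0.5 ||x - y||^2 + lambda * sum_i |x_{i+1} - x_i|`
#' exactly (Condat's direct algorithm).
#'
#' @param y numeric vector
#' @param lambda TV penalty weight (>= 0)
#' @return numeric vector of the same length
#' @export
prox_tv1d <- function(y, lambda) {
  stopifnot(lambda >= 0)
  cpp_tv1d(as.numeric(y), lambda)
}

#' Row/column alternating TV proximal step on a fluence map
#'
#' Applies the exact 1-D TV proximal operator along every row, then along
#' every column, then clamps at zero. This is the (approximate, alternating)
#' proximal map of the anisotropic total variation along the two orthogonal
#' leaf-travel axes; it drives fluence maps towards piecewise-constant,
#' rectangle-friendly structure.
#'
#' @param map numeric matrix (fluence map)
#' @param step proximal step size times the regularization strength (> 0;
#'   the limit `step -> 0` is the identity followed by clamping)
#' @return matrix of the same shape, nonnegative
#' @export
prox_tv_row_col <- function(map, step) {
  stopifnot(is.matrix(map), step >= 0)
  if (step > 0) {
    for (i in seq_len(nrow(map))) map[i, ] <- cpp_tv1d(map[i, ], step)
    for (j in seq_len(ncol(map))) map[, j] <- cpp_tv1d(map[, j], step)
  }
  pmin_zero <- map < 0
  map[pmin_zero] <- 0
  map
}

# anisotropic TV value of one map
tv_value <- function(map) {
  s <- 0
  if (nrow(map) > 1) s <- s + sum(abs(diff(map)))
  if (ncol(map) > 1) s <- s + sum(abs(diff(t(map))))
  s
}

#' Optimization objective for inverse fluence planning
#'
#' A weighted sum of one-sided quadratic voxel penalties plus an anisotropic
#' total-variation regularizer on each field's fluence map. Each term
#' penalizes, over the voxels of one structure, either underdose below a
#' goal (`type = "under"`: `(goal - d)_+^2`) or overdose above a goal
#' (`type = "over"`: `(d - goal)_+^2`), normalized by the structure's voxel
#' count.
#'
#' @param terms list of terms; each a list with `structure` (name, for
#'   reporting), `mask` (logical array on the grid) or `rows` (row indices
#'   into the influence support), `type` (`"under"`/`"over"`), `dose` (goal,
#'   Gy) and `weight` (> 0 for the PTV underdose term).
#' @param lambda TV regularization strength; `NULL` selects
#'   `lambda_rel * max |gradient at zero fluence|`.
#' @param lambda_rel relative regularization strength (default 0.05).
#' @param max_iter iteration cap (default 2000).
#' @param tol relative objective-change convergence tolerance (default 1e-6,
#'   sustained over 10 iterations).
#' @return object of class `objective_spec`
#' @export
objective_spec <- function(terms, lambda = NULL, lambda_rel = 0.05,
                           max_iter = 2000L, tol = 1e-6) {
  stopifnot(length(terms) >= 1, max_iter >= 1, tol > 0, lambda_rel >= 0)
  for (t in terms) {
    stopifnot(t$type %in% c("under", "over"), t$weight >= 0, t$dose >= 0)
  }
  if (!is.null(lambda)) stopifnot(lambda >= 0)
  structure(list(terms = terms, lambda = lambda, lambda_rel = lambda_rel,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "objective_spec")
}

# resolve masks to support-row indices; drop terms with no voxels
resolve_terms <- function(objective, influence) {
  terms <- lapply(objective$terms, function(t) {
    if (is.null(t$rows)) {
      t$rows <- match(which(t$mask), influence$support)
      t$rows <- t$rows[!is.na(t$rows)]
    }
    t$n <- length(t$rows)
    t
  })
  Filter(function(t) t$n > 0, terms)
}

# smooth objective part and voxel-space gradient weights for dose vector d
penalty_value <- function(terms, d) {
  s <- 0
  for (t in terms) {
    r <- if (t$type == "under") pmax(t$dose - d[t$rows], 0)
         else pmax(d[t$rows] - t$dose, 0)
    s <- s + t$weight / t$n * sum(r * r)
  }
  s
}

penalty_gradient_vox <- function(terms, d) {
  g <- numeric(length(d))
  for (t in terms) {
    if (t$type == "under") {
      r <- pmax(t$dose - d[t$rows], 0)
      g[t$rows] <- g[t$rows] - 2 * t$weight / t$n * r
    } else {
      r <- pmax(d[t$rows] - t$dose, 0)
      g[t$rows] <- g[t$rows] + 2 * t$weight / t$n * r
    }
  }
  g
}

# split/merge the concatenated fluence vector into per-field matrices
fluence_maps <- function(x, fields) {
  lapply(fields, function(f) matrix(x[f$cols], f$n1, f$n2))
}

prox_all_fields <- function(x, fields, step_lambda) {
  for (f in fields) {
    x[f$cols] <- prox_tv_row_col(matrix(x[f$cols], f$n1, f$n2), step_lambda)
  }
  x
}

tv_all_fields <- function(x, fields) {
  sum(vapply(fields, function(f) tv_value(matrix(x[f$cols], f$n1, f$n2)),
             numeric(1)))
}

#' FISTA fluence-map optimization
#'
#' Minimizes the composite objective (one-sided quadratic dose penalties +
#' anisotropic TV) over nonnegative per-field fluence maps by accelerated
#' proximal gradient (FISTA) with a monotone safeguard: a candidate iterate
#' is accepted only if it does not increase the objective; otherwise the
#' momentum is restarted and, if needed, the step is backtracked. The
#' optimizer is deterministic (cold start at zero fluence).
#'
#' @param influence a `dose_influence` from [assemble_influence()]
#' @param objective an [objective_spec()]
#' @return object of class `fluence_plan`: `maps` (list of per-field
#'   matrices), `x` (concatenated fluence vector), `trace` (objective per
#'   accepted iteration, nonincreasing), `lambda`, `converged`, `iterations`
#' @export
optimize_fluence <- function(influence, objective) {
  stopifnot(inherits(influence, "dose_influence"),
            inherits(objective, "objective_spec"))
  D <- influence$D
  fields <- influence$fields
  terms <- resolve_terms(objective, influence)
  if (length(terms) == 0) stop("no objective term overlaps the support")

  nvox <- nrow(D)
  x <- numeric(ncol(D))
  d0 <- numeric(nvox)

  g0 <- as.numeric(Matrix::crossprod(D, penalty_gradient_vox(terms, d0)))
  lambda <- objective$lambda
  if (is.null(lambda)) lambda <- objective$lambda_rel * max(abs(g0), 1e-12)

  # Lipschitz bound of the smooth part by power iteration on D' W D
  wv <- numeric(nvox)
  for (t in terms) wv[t$rows] <- wv[t$rows] + 2 * t$weight / t$n
  z <- rep(1 / sqrt(ncol(D)), ncol(D))
  L <- 1
  for (it in 1:12) {
    z2 <- as.numeric(Matrix::crossprod(D, wv * as.numeric(D %*% z)))
    L <- sqrt(sum(z2 * z2))
    if (L == 0) break
    z <- z2 / L
  }
  L <- max(L * 1.05, 1e-12)
  step <- 1 / L

  obj_at <- function(x, dx) penalty_value(terms, dx) + lambda * tv_all_fields(x, fields)

  Fx <- obj_at(x, d0)
  trace <- Fx
  y <- x
  tmom <- 1
  stall <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < objective$max_iter) {
    iter <- iter + 1L
    dy <- as.numeric(D %*% y)
    gy <- as.numeric(Matrix::crossprod(D, penalty_gradient_vox(terms, dy)))
    znew <- prox_all_fields(y - step * gy, fields, step * lambda)
    Fz <- obj_at(znew, as.numeric(D %*% znew))
    if (Fz > Fx + 1e-12 * max(1, abs(Fx))) {
      # momentum restart, then backtrack the step from the current iterate
      dx <- as.numeric(D %*% x)
      gx <- as.numeric(Matrix::crossprod(D, penalty_gradient_vox(terms, dx)))
      repeat {
        znew <- prox_all_fields(x - step * gx, fields, step * lambda)
        Fz <- obj_at(znew, as.numeric(D %*% znew))
        if (Fz <= Fx + 1e-12 * max(1, abs(Fx)) || step < 1e-14 / L) break
        step <- step / 2
      }
      tmom <- 1
      if (Fz > Fx) { znew <- x; Fz <- Fx }
    }
    tnew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    y <- znew + ((tmom - 1) / tnew) * (znew - x)
    rel <- (Fx - Fz) / max(abs(Fx), 1e-12)
    x <- znew
    Fx <- Fz
    tmom <- tnew
    trace <- c(trace, Fx)
    stall <- if (rel < objective$tol) stall + 1L else 0L
    if (stall >= 10L) { converged <- TRUE; break }
  }

  structure(
    list(maps = fluence_maps(x, fields), x = x, trace = trace,
         lambda = lambda, converged = converged, iterations = iter),
    class = "fluence_plan")
}

#' @export
print.fluence_plan <- function(x, ...) {
  cat("<fluence_plan> ", length(x$maps), " fields, ", x$iterations,
      " iterations, objective ", format(tail_value(x$trace)),
      if (!x$converged) " (iteration cap reached)", "\n", sep = "")
  invisible(x)
}

tail_value <- function(v) v[length(v)]
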