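#' Greedy rectangular-aperture decomposition of a fluence map
#'
#' Peels a nonnegative fluence map into weighted axis-aligned rectangles
#' deliverable by four orthogonal leaf pairs. Each step selects the
#' rectangle and weight maximizing the L1 residual reduction subject to the
#' residual staying nonnegative (weight = min of the residual over the
#' rectangle, so the reconstruction never exceeds the map); ties prefer the
#' larger area, then the smallest row-major origin. Stops when the L1
#' residual drops to `tol` times the map's L1 mass or the budget is hit.
#'
#' @param map nonnegative numeric matrix
#' @param tol relative L1 reconstruction tolerance in (0, 1)
#' @param budget maximum number of rectangles (>= 1)
#' @return object of class `rect_decomposition`: data frame `rectangles`
#'   with 1-based inclusive bounds (`row0`, `row1`, `col0`, `col1`) and
#'   `weight`; `achieved` (relative L1 residual); `budget_hit` flag
#' @export
decompose_rectangles <- function(map, tol = 0.02, budget = 128L) {
  stopifnot(is.matrix(map), all(map >= 0), tol > 0, tol < 1, budget >= 1)
  res <- cpp_peel_rectangles(map, tol, as.integer(budget))
  rect <- data.frame(row0 = res$r0 + 1L, row1 = res$r1 + 1L,
                     col0 = res$c0 + 1L, col1 = res$c1 + 1L,
                     weight = res$weight)
  achieved <- if (res$map_l1 > 0) res$residual_l1 / res$map_l1 else 0
  structure(list(rectangles = rect, achieved = achieved,
                 budget_hit = achieved > tol && nrow(rect) >= budget,
                 dim = dim(map)),
            class = "rect_decomposition")
}

#' Reconstruct a fluence map from weighted rectangles
#'
#' @param decomposition a `rect_decomposition`, or a data frame with
#'   `row0`, `row1`, `col0`, `col1`, `weight`
#' @param dim matrix dimensions (taken from the decomposition if absent)
#' @return numeric matrix, the exact weighted sum of rectangle indicators
#' @export
fluence_from_rectangles <- function(decomposition, dim = NULL) {
  rect <- if (inherits(decomposition, "rect_decomposition")) {
    if (is.null(dim)) dim <- decomposition$dim
    decomposition$rectangles
  } else decomposition
  stopifnot(!is.null(dim))
  out <- matrix(0, dim[1], dim[2])
  for (k in seq_len(nrow(rect))) {
    out[rect$row0[k]:rect$row1[k], rect$col0[k]:rect$col1[k]] <-
      out[rect$row0[k]:rect$row1[k], rect$col0[k]:rect$col1[k]] + rect$weight[k]
  }
  out
}

#' @export
print.rect_decomposition <- function(x, ...) {
  cat("<rect_decomposition> ", nrow(x$rectangles), " rectangles, relative L1 residual ",
      format(x$achieved, digits = 3),
      if (x$budget_hit) " (budget hit before tolerance)", "\n", sep = "")
  invisible(x)
}
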