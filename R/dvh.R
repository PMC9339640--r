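#' Cumulative dose-volume histogram
#'
#' `V(d)`: the fraction of the structure receiving at least dose `d`,
#' evaluated at uniform bin edges from 0 to just above the maximum dose.
#'
#' @param dose 3-D dose array (Gy)
#' @param mask logical structure mask (nonempty)
#' @param bin_width bin width in Gy
#' @param structure optional structure name carried on the curve
#' @param max_dose optional upper edge (Gy); defaults to the masked maximum
#' @return object of class `dvh`: `edges` (Gy), `volume_fraction`,
#'   `structure`
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1, structure = NULL,
                        max_dose = NULL) {
  if (!any(mask)) stop("empty mask")
  stopifnot(bin_width > 0)
  d <- dose[mask]
  top <- if (is.null(max_dose)) max(d) else max_dose
  edges <- seq(0, top + bin_width, by = bin_width)
  vf <- vapply(edges, function(e) mean(d >= e), numeric(1))
  structure(list(edges = edges, volume_fraction = vf,
                 structure = structure, bin_width = bin_width),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat("<dvh>", if (!is.null(x$structure)) x$structure, length(x$edges),
      "edges up to", format(max(x$edges)), "Gy\n")
  invisible(x)
}

#' @export
plot.dvh <- function(x, add = FALSE, ...) {
  if (add) graphics::lines(x$edges, 100 * x$volume_fraction, ...)
  else graphics::plot(x$edges, 100 * x$volume_fraction, type = "l",
                      xlab = "Dose (Gy)", ylab = "Volume (%)",
                      main = x$structure, ylim = c(0, 100), ...)
  invisible(x)
}

#' Median structure dose as percent of prescription (D50)
#'
#' @param dose 3-D dose array (Gy)
#' @param mask logical structure mask (nonempty)
#' @param prescription prescription dose, Gy (> 0)
#' @return `100 * median(dose[mask]) / prescription`; the median is the
#'   50th percentile with midpoint interpolation for even counts
#' @export
median_dose_percent <- function(dose, mask, prescription) {
  if (!any(mask)) stop("empty mask")
  stopifnot(prescription > 0)
  100 * stats::median(dose[mask]) / prescription
}

#' Mean structure dose as percent of prescription
#' @inheritParams median_dose_percent
#' @export
mean_dose_percent <- function(dose, mask, prescription) {
  if (!any(mask)) stop("empty mask")
  stopifnot(prescription > 0)
  100 * mean(dose[mask]) / prescription
}

#' Integral dose over a reference region, percent of prescription
#'
#' Mean dose over the integral-dose region (body minus skeletal bone minus
#' spleen), as a percentage of the prescription. Volume-weighted (every
#' voxel counts equally); mass weighting is deliberately not applied.
#'
#' @param dose 3-D dose array (Gy)
#' @param region logical mask of the reference region (nonempty)
#' @param prescription prescription dose, Gy
#' @export
integral_dose_percent <- function(dose, region, prescription) {
  if (!any(region)) stop("empty integral-dose region")
  stopifnot(prescription > 0)
  100 * mean(dose[region]) / prescription
}

#' D50 read off a cumulative DVH curve
#'
#' The largest bin edge at which at least half the volume is covered;
#' agrees with [median_dose_percent()] to within one bin width.
#'
#' @param dvh a [compute_dvh()] curve
#' @return dose in Gy
#' @export
dvh_d50 <- function(dvh) {
  i <- which(dvh$volume_fraction >= 0.5)
  dvh$edges[max(i)]
}

#' Pointwise average of DVH curves across subjects
#'
#' @param curves list of `dvh` objects sharing identical bin edges
#' @return a `dvh` whose volume fraction is the pointwise mean (still
#'   nonincreasing)
#' @export
average_dvh <- function(curves) {
  stopifnot(length(curves) >= 1)
  e <- curves[[1]]$edges
  for (c in curves) {
    if (!isTRUE(all.equal(c$edges, e))) stop("DVH curves have mismatched bins")
  }
  vf <- rowMeans(vapply(curves, `[[`, numeric(length(e)), "volume_fraction"))
  structure(list(edges = e, volume_fraction = vf,
                 structure = curves[[1]]$structure,
                 bin_width = curves[[1]]$bin_width),
            class = "dvh")
}
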