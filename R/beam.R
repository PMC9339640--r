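#' Beam geometry for one coplanar field
#'
#' Fields rotate about the cranio-caudal (z) axis. At gantry angle 0 the
#' source sits dorsal to the animal (+y) and the beam travels ventrally;
#' angles increase clockwise when viewed from the cranial side. The beamlet
#' lattice lives in the isocenter plane with axis `e1` transverse (in the
#' rotation plane) and `e2` along z; beamlet `(i, j)` has its center at
#' `offset + ((i-1) * size, (j-1) * size)` in (e1, e2) coordinates.
#'
#' @param angle_deg gantry angle in degrees, `[0, 360)`.
#' @param isocenter world point (mm).
#' @param sid source-to-isocenter distance in mm (default 305.4).
#' @param n1,n2 beamlet lattice dimensions along `e1` (transverse) and `e2`
#'   (cranio-caudal).
#' @param beamlet_mm beamlet side at the isocenter plane (default 1 mm).
#' @param offset numeric length 2: (e1, e2) coordinate of the center of
#'   beamlet (1, 1), mm. Defaults to centering the lattice on the axis.
#' @param max_field_mm maximum field side (default 120 mm).
#' @return object of class `beam_geometry`
#' @export
beam_geometry <- function(angle_deg, isocenter, sid = 305.4,
                          n1 = 1L, n2 = 1L, beamlet_mm = 1.0,
                          offset = NULL, max_field_mm = 120) {
  stopifnot(angle_deg >= 0, angle_deg < 360, length(isocenter) == 3L,
            sid > 0, n1 >= 1, n2 >= 1, beamlet_mm > 0)
  if (n1 * beamlet_mm > max_field_mm || n2 * beamlet_mm > max_field_mm) {
    stop("beamlet lattice exceeds the maximum field side of ",
         max_field_mm, " mm")
  }
  th <- angle_deg * pi / 180
  u <- c(sin(th), cos(th), 0)           # isocenter -> source
  e1 <- c(cos(th), -sin(th), 0)
  e2 <- c(0, 0, 1)
  if (is.null(offset)) {
    offset <- c(-(n1 - 1) / 2 * beamlet_mm, -(n2 - 1) / 2 * beamlet_mm)
  }
  structure(
    list(angle_deg = angle_deg, isocenter = as.numeric(isocenter), sid = sid,
         source = as.numeric(isocenter) + sid * u,
         e1 = e1, e2 = e2, n1 = as.integer(n1), n2 = as.integer(n2),
         beamlet_mm = beamlet_mm, offset = as.numeric(offset)),
    class = "beam_geometry")
}

#' The seven equally distributed coplanar fields of a marrow-conformal plan
#'
#' @param isocenter world point (mm)
#' @param ... passed to [beam_geometry()] (lattice size etc.)
#' @return list of 7 `beam_geometry` objects at angles k*360/7, k = 0..6
#' @export
seven_field_geometry <- function(isocenter, ...) {
  lapply(0:6, function(k) beam_geometry(k * 360 / 7, isocenter, ...))
}

#' kV attenuation and deposition model
#'
#' Mono-energetic primary-photon model at the beam's effective energy, with
#' per-material dose-to-medium enhancement factors and a Gaussian lateral
#' scatter kernel parameterised in the isocenter plane. The bone factor
#' (default 2.8) reflects the strong photoelectric absorption of ~80 keV
#' photons in cortical bone, which receives well over 250% of the
#' soft-tissue dose at equal depth.
#'
#' @param energy_kev effective photon energy (informational; default 78.8).
#' @param mu_water mass attenuation coefficient of water at the effective
#'   energy, cm^2/g (default 0.1835).
#' @param enhancement named numeric: dose enhancement relative to water for
#'   `soft`, `lung`, `bone` media (bone must exceed 1).
#' @param sigma_mm lateral kernel sigma at the isocenter plane, mm.
#' @param cutoff_sigma kernel truncation radius in sigmas.
#' @param calibration Gy delivered per unit beamlet weight at the isocenter
#'   by an unattenuated central beamlet; the absolute scale is conventional
#'   (all reported metrics are % of prescription).
#' @param sparsity_floor per-column relative floor below which influence
#'   entries are dropped.
#' @return object of class `attenuation_model`
#' @export
attenuation_model <- function(energy_kev = 78.8, mu_water = 0.1835,
                              enhancement = c(soft = 1.0, lung = 1.0, bone = 2.8),
                              sigma_mm = 0.8, cutoff_sigma = 3.5,
                              calibration = 1.0, sparsity_floor = 1e-4) {
  stopifnot(mu_water > 0, all(enhancement > 0), sigma_mm > 0,
            cutoff_sigma > 0, calibration > 0, sparsity_floor >= 0)
  if (enhancement[["bone"]] <= 1) {
    stop("bone enhancement factor must exceed 1")
  }
  structure(
    list(energy_kev = energy_kev, mu_water = mu_water,
         enhancement = enhancement, sigma_mm = sigma_mm,
         cutoff_sigma = cutoff_sigma, calibration = calibration,
         sparsity_floor = sparsity_floor),
    class = "attenuation_model")
}
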