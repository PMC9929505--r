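# Muscle architecture and physiology: pennation kinematics, fibre-length
# kinematics for direct and filament attachment, the Gaussian force-length
# relation, and the physiological cross-sectional area.

#' Muscle fibre population
#'
#' A homogeneous group of muscle fibres described by its reference pennation
#' angle, reference fibre length, filament length (0 for directly attached
#' fibres) and its share of the muscle's fibres. The total attachment length
#' at the reference pose is `fibre_length0 + filament_length`.
#'
#' @param phi0_deg reference pennation angle, degrees, in \[0, 90).
#' @param fibre_length0 reference fibre length (mm), > 0.
#' @param filament_length filament length (mm), >= 0; 0 means direct
#'   attachment.
#' @param number_fraction share of the muscle's fibres in this population,
#'   in (0, 1\].
#' @return An object of class `fibre_population`.
#' @export
fibre_population <- function(phi0_deg, fibre_length0, filament_length = 0,
                             number_fraction = 1) {
  phi0_deg <- check_scalar(phi0_deg, "phi0_deg", nonneg = TRUE)
  if (phi0_deg >= 90) bm_stop("'phi0_deg' must be < 90 degrees")
  fibre_length0 <- check_scalar(fibre_length0, "fibre_length0", positive = TRUE)
  filament_length <- check_scalar(filament_length, "filament_length", nonneg = TRUE)
  number_fraction <- check_scalar(number_fraction, "number_fraction", positive = TRUE)
  if (number_fraction > 1) bm_stop("'number_fraction' must be <= 1")
  structure(list(
    phi0_deg = phi0_deg,
    fibre_length0 = fibre_length0,
    filament_length = filament_length,
    number_fraction = number_fraction
  ), class = "fibre_population")
}

#' Force-length parameters
#'
#' The three physiological parameters of the Gaussian force-length curve
#' `sigma(L) = sigma_max * exp(-beta * (1 - L / L_opt)^2)`.
#'
#' @param sigma_max peak isometric muscle stress (MPa), > 0.
#' @param l_opt optimal fibre length (mm), > 0.
#' @param beta dimensionless shape parameter, > 0; larger values mean a
#'   faster decay of stress away from `l_opt`.
#' @return An object of class `force_length_params`.
#' @export
force_length_params <- function(sigma_max, l_opt, beta) {
  structure(list(
    sigma_max = check_scalar(sigma_max, "sigma_max", positive = TRUE),
    l_opt = check_scalar(l_opt, "l_opt", positive = TRUE),
    beta = check_scalar(beta, "beta", positive = TRUE)
  ), class = "force_length_params")
}

#' @export
print.force_length_params <- function(x, ...) {
  cat(sprintf("Force-length parameters: sigma_max = %.4g MPa, L_opt = %.4g mm, beta = %.4g\n",
              x$sigma_max, x$l_opt, x$beta))
  invisible(x)
}

#' Muscle architecture
#'
#' Muscle volume plus one or more fibre populations. The first population
#' (or the one named by `reference`) is the reference population: the
#' physiological cross-sectional area of the muscle is defined as
#' `volume / L_opt` with the optimal fibre length of that population, and
#' optimal lengths of the other populations are tied to it by equivalent
#' stretch (the ratio of reference fibre lengths).
#'
#' @param volume muscle volume (mm^3), > 0.
#' @param populations a list of [fibre_population()] objects whose
#'   `number_fraction`s sum to 1.
#' @param reference index of the reference population (default 1).
#' @return An object of class `muscle_architecture`.
#' @export
muscle_architecture <- function(volume, populations, reference = 1L) {
  volume <- check_scalar(volume, "volume", positive = TRUE)
  if (inherits(populations, "fibre_population")) populations <- list(populations)
  if (!length(populations) ||
      !all(vapply(populations, inherits, logical(1), "fibre_population"))) {
    bm_stop("'populations' must be a list of fibre_population objects")
  }
  fr <- vapply(populations, `[[`, numeric(1), "number_fraction")
  if (abs(sum(fr) - 1) > 1e-6) {
    bm_stop(sprintf("population number fractions must sum to 1 (got %g)", sum(fr)))
  }
  reference <- as.integer(reference)
  if (reference < 1L || reference > length(populations)) {
    bm_stop("'reference' must index one of the populations")
  }
  structure(list(volume = volume, populations = populations,
                 reference = reference),
            class = "muscle_architecture")
}

#' Pennation angle after an apodeme displacement
#'
#' As the apodeme displaces by `delta`, fibres attached at reference
#' pennation angle `phi0` rotate to
#' `phi = arctan(sin(phi0) / (cos(phi0) - delta / total_length0))`.
#' The angle is mapped to (0, 180) degrees: when the denominator becomes
#' negative the fibre has rotated past perpendicular and the returned angle
#' exceeds 90 degrees, which preserves the fibre-height invariant
#' `total_length * sin(phi) = total_length0 * sin(phi0)`.
#'
#' @param delta apodeme displacement(s) (mm); vectorized. Positive values
#'   correspond to mandible closing.
#' @param phi0_deg reference pennation angle, degrees.
#' @param total_length0 reference distance between fibre origin and apodeme
#'   insertion (fibre plus filament), mm, > 0.
#' @return Pennation angle(s) in degrees.
#' @examples
#' pennation_angle(0, 30, 2)             # 30
#' pennation_angle(0.4, 30, 2)           # 36.9
#' @export
pennation_angle <- function(delta, phi0_deg, total_length0) {
  phi0_deg <- check_scalar(phi0_deg, "phi0_deg", nonneg = TRUE)
  total_length0 <- check_scalar(total_length0, "total_length0", positive = TRUE)
  phi0 <- deg2rad(phi0_deg)
  den <- cos(phi0) - delta / total_length0
  if (sin(phi0) == 0 && any(abs(den) < 1e-12)) {
    bm_stop("fibre orientation undefined: sin(phi0) = 0 and displaced length is 0",
            class = "bitemech_degenerate_error")
  }
  # atan2 selects the branch: den < 0 gives angles in (90, 180) degrees
  rad2deg(atan2(sin(phi0), den))
}

#' Fibre length after an apodeme displacement
#'
#' For a fibre attached via a filament of constant length `L_fil`, with
#' total reference attachment length `L_t0 = L_0 + L_fil`, the fibre length
#' after an apodeme displacement `delta` is
#' `sqrt((cos(phi0) L_t0 - delta)^2 + (sin(phi0) L_t0)^2) - L_fil`.
#' With `filament_length = 0` this reduces exactly to the directly-attached
#' relation.
#'
#' @param delta apodeme displacement(s) (mm); vectorized.
#' @param pop a [fibre_population()].
#' @return Fibre length(s) in mm.
#' @export
fibre_length <- function(delta, pop) {
  stopifnot(inherits(pop, "fibre_population"))
  phi0 <- deg2rad(pop$phi0_deg)
  lt0 <- pop$fibre_length0 + pop$filament_length
  lf <- sqrt((cos(phi0) * lt0 - delta)^2 + (sin(phi0) * lt0)^2) -
    pop$filament_length
  if (any(lf <= 0)) {
    bm_stop("non-physical displacement: fibre length would be <= 0",
            class = "bitemech_numerical_error")
  }
  lf
}

#' Gaussian force-length muscle stress
#'
#' `sigma(L) = sigma_max * exp(-beta (1 - L / L_opt)^2)`: maximal (equal to
#' `sigma_max`) at `L = L_opt`, strictly positive, and symmetric in the
#' normalized length deviation `1 - L / L_opt`.
#'
#' @param fibre_len fibre length(s) (mm), > 0; vectorized.
#' @param params a [force_length_params()].
#' @return Muscle stress in MPa.
#' @examples
#' p <- force_length_params(1.16, 0.92, 5.34)
#' stress(0.92, p)  # 1.16
#' @export
stress <- function(fibre_len, params) {
  stopifnot(inherits(params, "force_length_params"))
  if (any(fibre_len <= 0)) bm_stop("'fibre_len' must be > 0")
  params$sigma_max * exp(-params$beta * (1 - fibre_len / params$l_opt)^2)
}

#' Physiological cross-sectional area
#'
#' `A_phys = volume / l_opt`: the cross-sectional area the muscle has when
#' its fibres are at optimal length. Because muscle is incompressible, this
#' area is strain-invariant and is the natural area to pair with the peak
#' stress `sigma_max`.
#'
#' @param volume muscle volume (mm^3), > 0.
#' @param l_opt optimal fibre length (mm), > 0.
#' @return Area in mm^2.
#' @examples
#' physiological_cross_section(3.956, 0.92)  # 4.3
#' @export
physiological_cross_section <- function(volume, l_opt) {
  volume <- check_scalar(volume, "volume", positive = TRUE)
  l_opt <- check_scalar(l_opt, "l_opt", positive = TRUE)
  volume / l_opt
}
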