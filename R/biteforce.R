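# Forward bite-force model, sensor-projection corrections, minimal model and
# allometric bounds.

#' Bite apparatus
#'
#' The complete geometric and muscular description of one head side,
#' sufficient to evaluate the forward model
#' `|F_b|(theta) = sigma(theta) A_phys cos(phi(theta)) MA(theta)`.
#' Optimal fibre lengths of non-reference populations are tied to the
#' reference population's `l_opt` by equivalent stretch: they are scaled by
#' the ratio of reference-pose fibre lengths.
#'
#' @param frame a [joint_frame()].
#' @param levers a [lever_set()].
#' @param muscle a [muscle_architecture()].
#' @param physiology a [force_length_params()] for the reference population.
#' @param theta_range admissible opening-angle range in degrees
#'   (default `c(35, 105)`, the range over which the geometric relations were
#'   validated).
#' @param pooled_area if `TRUE` (default) the physiological cross-sectional
#'   area is the pooled `volume / l_opt` of the reference population,
#'   partitioned across populations by `number_fraction`; if `FALSE`, each
#'   population's share of the volume is divided by its own tied `l_opt`.
#' @return An object of class `bite_apparatus` with the derived field
#'   `a_phys` (mm^2).
#' @export
bite_apparatus <- function(frame, levers, muscle, physiology,
                           theta_range = c(35, 105), pooled_area = TRUE) {
  stopifnot(inherits(frame, "joint_frame"), inherits(levers, "lever_set"),
            inherits(muscle, "muscle_architecture"),
            inherits(physiology, "force_length_params"))
  if (!is.numeric(theta_range) || length(theta_range) != 2L ||
      theta_range[1] >= theta_range[2]) {
    bm_stop("'theta_range' must be an increasing pair of angles in degrees")
  }
  structure(list(
    frame = frame, levers = levers, muscle = muscle, physiology = physiology,
    theta_range = as.numeric(theta_range), pooled_area = isTRUE(pooled_area),
    a_phys = physiological_cross_section(muscle$volume, physiology$l_opt)
  ), class = "bite_apparatus")
}

#' @export
print.bite_apparatus <- function(x, ...) {
  cat("Bite apparatus\n")
  cat(sprintf("  theta range    : %g-%g deg\n", x$theta_range[1], x$theta_range[2]))
  cat(sprintf("  muscle volume  : %.4g mm^3, A_phys = %.4g mm^2\n",
              x$muscle$volume, x$a_phys))
  cat(sprintf("  physiology     : sigma_max = %.4g MPa, L_opt = %.4g mm, beta = %.4g\n",
              x$physiology$sigma_max, x$physiology$l_opt, x$physiology$beta))
  cat(sprintf("  populations    : %d (reference: %d)\n",
              length(x$muscle$populations), x$muscle$reference))
  invisible(x)
}

# per-population optimal lengths and area shares implied by the apparatus
population_physiology <- function(apparatus) {
  mus <- apparatus$muscle
  ref <- mus$populations[[mus$reference]]
  l0_ref <- ref$fibre_length0
  lapply(mus$populations, function(pop) {
    stretch <- pop$fibre_length0 / l0_ref
    l_opt <- apparatus$physiology$l_opt * stretch
    area <- if (apparatus$pooled_area) {
      apparatus$a_phys * pop$number_fraction
    } else {
      pop$number_fraction * mus$volume / l_opt
    }
    list(pop = pop, l_opt = l_opt, area = area)
  })
}

#' Forward bite-force model
#'
#' Evaluates `|F_b|(theta) = MA(theta) * sum over populations of
#' sigma(L_pop(theta)) A_pop cos(phi_pop(theta))`. Stress, fibre length and
#' pennation follow the population's attachment mode (direct or filament);
#' the mechanical advantage is shared.
#'
#' @param theta_deg opening angle(s) in degrees; must lie within the
#'   apparatus' admissible `theta_range`.
#' @param apparatus a [bite_apparatus()].
#' @param terms if `TRUE`, return the per-angle decomposition (mechanical
#'   advantage, area-weighted `cos(phi)` and stress, apodeme displacement)
#'   alongside the force.
#' @return A numeric vector of bite forces (N), or a [tibble::tibble] with
#'   columns `theta_deg`, `force`, `mechanical_advantage`, `cos_phi`,
#'   `sigma_mpa`, `delta` when `terms = TRUE`.
#' @examples
#' app <- make_reference_apparatus()
#' bite_force(c(50, 75, 100), app)
#' @export
bite_force <- function(theta_deg, apparatus, terms = FALSE) {
  stopifnot(inherits(apparatus, "bite_apparatus"))
  rng <- apparatus$theta_range
  if (any(theta_deg < rng[1] - 1e-9 | theta_deg > rng[2] + 1e-9)) {
    bm_stop(sprintf("opening angle outside the admissible range [%g, %g] deg",
                    rng[1], rng[2]))
  }
  lev <- effective_levers(theta_deg, apparatus$levers, apparatus$frame)
  delta <- apodeme_displacement(theta_deg, apparatus$levers, apparatus$frame)$delta
  pops <- population_physiology(apparatus)
  apo_force <- 0
  cos_phi_w <- 0
  sigma_w <- 0
  total_area <- sum(vapply(pops, `[[`, numeric(1), "area"))
  for (pp in pops) {
    lt0 <- pp$pop$fibre_length0 + pp$pop$filament_length
    lf <- fibre_length(delta, pp$pop)
    phi <- pennation_angle(delta, pp$pop$phi0_deg, lt0)
    sg <- stress(lf, force_length_params(apparatus$physiology$sigma_max,
                                         pp$l_opt,
                                         apparatus$physiology$beta))
    apo_force <- apo_force + pp$area * sg * cos(deg2rad(phi))
    cos_phi_w <- cos_phi_w + pp$area * cos(deg2rad(phi))
    sigma_w <- sigma_w + pp$area * sg
  }
  force <- lev$mechanical_advantage * apo_force
  if (!terms) return(force)
  tibble::tibble(
    theta_deg = theta_deg,
    force = force,
    mechanical_advantage = lev$mechanical_advantage,
    cos_phi = cos_phi_w / total_area,
    sigma_mpa = sigma_w / total_area,
    delta = delta
  )
}

#' Bite measurement
#'
#' One in vivo bite-force observation from a one-dimensional sensor,
#' together with the geometry required to recover the bite-force magnitude.
#'
#' @param theta_deg mandibular opening angle at peak force, degrees.
#' @param force_measured measured force magnitude (N), >= 0.
#' @param outlever numeric 3-vector, joint centre to bite contact point (mm).
#' @param sensor_axis numeric 3-vector, the sensor's force-sensitive axis;
#'   normalized internally.
#' @param plate_moment_cal moment arm used for sensor calibration (mm), > 0.
#' @param plate_moment_bite moment arm of the mandible contact point on the
#'   bite plate (mm), > 0.
#' @param contact `"distal"` when the bite was transmitted by the most
#'   distal tooth, `"other"` otherwise.
#' @return An object of class `bite_measurement`.
#' @export
bite_measurement <- function(theta_deg, force_measured, outlever, sensor_axis,
                             plate_moment_cal = 1, plate_moment_bite = 1,
                             contact = c("distal", "other")) {
  contact <- match.arg(contact)
  force_measured <- check_scalar(force_measured, "force_measured", nonneg = TRUE)
  structure(list(
    theta_deg = check_scalar(theta_deg, "theta_deg"),
    force_measured = force_measured,
    outlever = check_vec3(outlever, "outlever"),
    sensor_axis = unit_vec(check_vec3(sensor_axis, "sensor_axis"), "sensor_axis"),
    plate_moment_cal = check_scalar(plate_moment_cal, "plate_moment_cal", positive = TRUE),
    plate_moment_bite = check_scalar(plate_moment_bite, "plate_moment_bite", positive = TRUE),
    contact = contact
  ), class = "bite_measurement")
}

#' Recover bite force from a one-dimensional sensor measurement
#'
#' The bite force is perpendicular to both the outlever and the rotation
#' axis, so its orientation is `Lo x R`. A one-dimensional sensor measures
#' the projection of the bite force onto its sensitive axis, giving
#' `|F_b| = Gamma |F_m| / cos(alpha)` where `alpha` is the angle between the
#' sensitive axis and `Lo x R`, and `Gamma = L_p,cal / L_p,b` corrects for
#' the difference between calibration and bite moment arms on the bite
#' plate.
#'
#' @param meas a [bite_measurement()].
#' @param frame a [joint_frame()] providing the rotation axis.
#' @param cos_alpha_floor smallest admissible `cos(alpha)` (default 0.2);
#'   measurements closer to perpendicular are rejected as unusable rather
#'   than silently amplified.
#' @return Bite-force magnitude in N.
#' @export
measured_to_bite <- function(meas, frame, cos_alpha_floor = 0.2) {
  stopifnot(inherits(meas, "bite_measurement"), inherits(frame, "joint_frame"))
  fb_dir <- cross3(meas$outlever, frame$axis)
  nrm <- vec_norm(fb_dir)
  if (nrm < PROJECTION_TOL) {
    bm_stop("outlever is parallel to the rotation axis; bite-force direction undefined",
            class = "bitemech_degenerate_error")
  }
  cos_alpha <- sum(fb_dir / nrm * meas$sensor_axis)
  if (cos_alpha <= cos_alpha_floor) {
    bm_stop(sprintf(
      "sensor nearly perpendicular to the bite force (cos(alpha) = %.3f <= floor %.3f); measurement unusable",
      cos_alpha, cos_alpha_floor), class = "bitemech_numerical_error")
  }
  gamma_corr <- meas$plate_moment_cal / meas$plate_moment_bite
  gamma_corr * meas$force_measured / cos_alpha
}

#' Rescale a bite at a non-distal contact point to the distal tooth
#'
#' Stimulated bites do not always occur at the most distal tooth; the
#' measured force is rescaled by the ratio of effective outlevers,
#' `|F_b,s| = |F_b| |L_o,c,eff| / |L_o,d,eff|`.
#'
#' @param force bite force at the actual contact point (N).
#' @param outlever_contact_eff effective outlever at the contact point (mm),
#'   > 0.
#' @param outlever_distal_eff effective outlever at the distal tooth tip
#'   (mm), > 0.
#' @return Rescaled force in N.
#' @export
stimulated_rescale <- function(force, outlever_contact_eff, outlever_distal_eff) {
  outlever_contact_eff <- check_scalar(outlever_contact_eff,
                                       "outlever_contact_eff", positive = TRUE)
  outlever_distal_eff <- check_scalar(outlever_distal_eff,
                                      "outlever_distal_eff", positive = TRUE)
  force * outlever_contact_eff / outlever_distal_eff
}

#' Minimal-model inputs
#'
#' Head dimensions, sarcomere length and body mass used by the minimal
#' bite-force model and the allometric bounds.
#'
#' @param head_width,head_length,head_height head dimensions (mm), > 0.
#' @param sarcomere_length average sarcomere length (micrometres); the
#'   stress proxy is valid for 3-17 micrometres.
#' @param body_mass body mass (kg), > 0.
#' @return An object of class `minimal_model_inputs`.
#' @export
minimal_model_inputs <- function(head_width, head_length, head_height,
                                 sarcomere_length, body_mass) {
  structure(list(
    head_width = check_scalar(head_width, "head_width", positive = TRUE),
    head_length = check_scalar(head_length, "head_length", positive = TRUE),
    head_height = check_scalar(head_height, "head_height", positive = TRUE),
    sarcomere_length = check_scalar(sarcomere_length, "sarcomere_length", positive = TRUE),
    body_mass = check_scalar(body_mass, "body_mass", positive = TRUE)
  ), class = "minimal_model_inputs")
}

#' Sarcomere-length stress proxy
#'
#' Peak muscle stress estimated from average sarcomere length:
#' `sigma_max = 50 * S_l` kPa with `S_l` in micrometres, valid for
#' `3 <= S_l <= 17`.
#'
#' @param sarcomere_length sarcomere length in micrometres.
#' @return Estimated peak stress in kPa.
#' @export
sarcomere_stress <- function(sarcomere_length) {
  sarcomere_length <- check_scalar(sarcomere_length, "sarcomere_length",
                                   positive = TRUE)
  if (sarcomere_length < 3 || sarcomere_length > 17) {
    bm_stop(sprintf(
      "sarcomere length %g um outside the stress proxy's validity range [3, 17] um",
      sarcomere_length))
  }
  50 * sarcomere_length
}

#' Minimal model for the maximum bite force
#'
#' An upper-bound estimate of the maximum bite force from head width, head
#' length and sarcomere length alone:
#' `F_max = 0.55 * 1 * 0.3 Hw Hl * 50 Sl ~= 8.25 kPa/um * Hw Hl Sl`,
#' combining a mid-range mechanical advantage (0.55), `cos(phi) ~= 1`, the
#' head-size proxy for the physiological cross-section (`0.3 Hw Hl`) and the
#' sarcomere-length stress proxy.
#'
#' @param inputs a [minimal_model_inputs()].
#' @return Estimated maximum bite force in N.
#' @examples
#' inp <- minimal_model_inputs(2.2, 2.9, 1.8, 10, 55e-6)
#' minimal_max_force(inp)
#' @export
minimal_max_force <- function(inputs) {
  stopifnot(inherits(inputs, "minimal_model_inputs"))
  stress_kpa <- sarcomere_stress(inputs$sarcomere_length)
  area_mm2 <- 0.3 * inputs$head_width * inputs$head_length
  # kPa * mm^2 = 1e-3 N
  0.55 * 1 * area_mm2 * stress_kpa * 1e-3
}

#' Allometric bound on weight-specific force
#'
#' Across animals spanning ten orders of magnitude in mass, maximum
#' weight-specific forces are bounded by `coefficient * m^(-1/3)` with `m`
#' in kg; coefficient 20 bounds weight-specific *bite* force and 50 bounds
#' weight-specific *muscle* force.
#'
#' @param mass body mass in kg, > 0.
#' @param coefficient dimensionless bound coefficient (default 20).
#' @return Dimensionless weight-specific force bound.
#' @examples
#' allometric_bound(55e-6, 20)  # about 500
#' allometric_bound(55e-6, 50)  # about 1300
#' @export
allometric_bound <- function(mass, coefficient = 20) {
  mass <- check_scalar(mass, "mass", positive = TRUE)
  coefficient <- check_scalar(coefficient, "coefficient")
  coefficient * mass^(-1 / 3)
}
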