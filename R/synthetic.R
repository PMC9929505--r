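# Synthetic-data generators: a reference apparatus back-solved from the
# published summary morphology of the Atta cephalotes major bite apparatus,
# simulated bite-force data sets, rigid multi-pose landmark series and
# pennate fibre fields with ground truth.

# Back-solve a self-consistent apparatus from published summary quantities:
#   - the mechanical advantage peaks at 0.29 at theta = 51 deg, where the
#     apodeme angle is 90 deg -> reference pose theta0 = 51, gamma0 = 90 and
#     MA_max = |RxLi||RxA| / |RxLo| = 0.29;
#   - the apodeme displaces by 0.7 mm between theta = 35 and 105 deg, which
#     fixes |RxLi||RxA| = 0.7 / (cos(36 deg) - cos(106 deg)) = 0.6454 mm and
#     hence |RxLo| = 2.2254 mm;
#   - maximum total attachment lengths (at theta = 105 deg) of 2.11 mm
#     (direct) and 2.07 mm (filament-attached, of which 0.60 mm filament),
#     with largest/smallest fibre-length ratios 1.41 and 1.73, pin down each
#     population's rigid fibre triangle (constant height h over the apodeme,
#     longitudinal foot x displaced by Delta), and thereby the reference
#     fibre lengths and pennation angles at theta0;
#   - 15% of fibres attach directly, 85% via filaments;
#   - physiology from the published force-length fit (sigma_max = 1.16 MPa,
#     L_opt = 0.92 mm for the filament population, beta = 5.34) and
#     A_phys = 4.3 mm^2 -> muscle volume = 4.3 * 0.92 = 3.956 mm^3.
solve_reference_geometry <- function() {
  theta0 <- 51
  gamma0 <- 90
  gamma_at <- function(theta) deg2rad(theta0 - theta + gamma0)
  # Delta(theta) per unit |RxLi||RxA|
  delta_unit <- function(theta) cos(deg2rad(gamma0)) - cos(gamma_at(theta))
  k <- 0.7 / (delta_unit(35) - delta_unit(105))
  out_eff <- k / 0.29
  d35 <- k * delta_unit(35)
  d105 <- k * delta_unit(105)

  # rigid fibre triangle from the two extreme lengths; x = longitudinal foot
  solve_triangle <- function(lt_max, lt_min) {
    dx <- d35 - d105                         # x(105) - x(35) = 0.7 mm
    xsum <- (lt_max^2 - lt_min^2) / dx
    x105 <- (xsum + dx) / 2
    h <- sqrt(lt_max^2 - x105^2)
    x0 <- x105 + d105                        # x at the reference pose
    list(lt0 = sqrt(x0^2 + h^2), phi0 = rad2deg(atan2(h, x0)), height = h)
  }
  l_fil <- 0.60
  fil_total_max <- 2.07
  fil <- solve_triangle(fil_total_max,
                        (fil_total_max - l_fil) / 1.73 + l_fil)
  dir_total_max <- 2.11
  dir <- solve_triangle(dir_total_max, dir_total_max / 1.41)
  list(theta0 = theta0, gamma0 = gamma0, k = k, out_eff = out_eff,
       fil = fil, dir = dir, l_fil = l_fil)
}

#' Reference bite apparatus
#'
#' A fully specified bite apparatus back-solved from the published summary
#' morphology and physiology of the leaf-cutter ant (*Atta cephalotes*
#' major) mandible closer system: the mechanical advantage peaks at 0.29 at
#' a 51 degree opening angle (apodeme angle 90 degrees), the apodeme
#' displaces by 0.7 mm across the 35-105 degree opening range, maximum
#' total fibre lengths are 2.11 mm (direct) and 2.07 mm (filament-attached,
#' filament 0.60 mm), fibre-length ratios are 1.41 and 1.73, 15% of fibres
#' attach directly, and the force-length physiology is
#' `sigma_max = 1.16 MPa`, `L_opt = 0.92 mm`, `beta = 5.34` with
#' `A_phys = 4.3 mm^2`. Quantities not fixed by those constraints (e.g. the
#' exact lever directions) are chosen in a canonical frame: rotation axis
#' `(0, 0, 1)`, apodeme axis `(1, 0, 0)`, levers in the rotation plane.
#'
#' @param theta_range admissible opening-angle range (default `c(35, 105)`,
#'   the validated range).
#' @return A [bite_apparatus()].
#' @examples
#' app <- make_reference_apparatus()
#' effective_levers(51, app$levers, app$frame)$mechanical_advantage  # 0.29
#' @export
make_reference_apparatus <- function(theta_range = c(35, 105)) {
  geo <- solve_reference_geometry()
  frame <- joint_frame(c(0, 0, 0), c(0, 0, 1))
  # |R x A| = 1 and |R x Li| = k: inlever perpendicular to the apodeme axis
  # in the rotation plane realizes gamma0 = 90 deg geometrically
  levers <- lever_set(
    inlever = c(0, geo$k, 0),
    outlever_distal = geo$out_eff * c(cos(deg2rad(geo$theta0)),
                                      -sin(deg2rad(geo$theta0)), 0),
    outlever_proximal = 0.6 * geo$out_eff * c(cos(deg2rad(geo$theta0 - 15)),
                                              -sin(deg2rad(geo$theta0 - 15)), 0),
    apodeme_axis = c(1, 0, 0),
    gamma0_deg = geo$gamma0,
    theta0_deg = geo$theta0
  )
  muscle <- muscle_architecture(
    volume = 4.3 * 0.92,
    populations = list(
      fibre_population(phi0_deg = geo$fil$phi0,
                       fibre_length0 = geo$fil$lt0 - geo$l_fil,
                       filament_length = geo$l_fil,
                       number_fraction = 0.85),
      fibre_population(phi0_deg = geo$dir$phi0,
                       fibre_length0 = geo$dir$lt0,
                       filament_length = 0,
                       number_fraction = 0.15)
    ),
    reference = 1L
  )
  physiology <- force_length_params(sigma_max = 1.16, l_opt = 0.92,
                                    beta = 5.34)
  bite_apparatus(frame, levers, muscle, physiology,
                 theta_range = theta_range)
}

#' Simulate bite-force measurements
#'
#' Draws opening angles uniformly within `theta_range`, evaluates the
#' forward model and applies multiplicative Gaussian noise,
#' `F = F_model * (1 + e)`, `e ~ N(0, noise_scale)`, redrawn where the
#' result would be non-positive. With the default sensor geometry
#' (`cos(alpha) = 1`, `Gamma = 1`) the simulated measured force equals the
#' bite force.
#'
#' @param apparatus a [bite_apparatus()].
#' @param n number of measurements (default 138, the study's sample size).
#' @param theta_range sampling range of opening angles in degrees (default
#'   `c(50, 105)`, the measured range).
#' @param noise_scale standard deviation of the multiplicative noise
#'   (default 0.05).
#' @param seed integer seed (required: every stochastic routine in the
#'   package takes an explicit seed).
#' @return A [tibble::tibble] with columns `theta_deg`, `force` (noisy bite
#'   force, N), `force_true` (noise-free model force, N), `cos_alpha`,
#'   `gamma_correction`.
#' @export
simulate_bite_measurements <- function(apparatus, n = 138,
                                       theta_range = c(50, 105),
                                       noise_scale = 0.05, seed) {
  stopifnot(inherits(apparatus, "bite_apparatus"))
  if (missing(seed)) bm_stop("'seed' is required")
  noise_scale <- check_scalar(noise_scale, "noise_scale", nonneg = TRUE)
  set.seed(as.integer(seed))
  theta <- runif(n, theta_range[1], theta_range[2])
  f_true <- bite_force(theta, apparatus)
  f <- f_true * (1 + rnorm(n, 0, noise_scale))
  while (any(bad <- f <= 0)) {
    f[bad] <- f_true[bad] * (1 + rnorm(sum(bad), 0, noise_scale))
  }
  tibble::tibble(theta_deg = theta, force = f, force_true = f_true,
                 cos_alpha = 1, gamma_correction = 1)
}

# Rodrigues rotation of row-vector matrix about unit axis by angle (radians)
rotate_about <- function(m, axis, angle) {
  axis <- unit_vec(axis, "axis")
  ca <- cos(angle)
  sa <- sin(angle)
  t(apply(m, 1, function(v) {
    v * ca + cross3(axis, v) * sa + axis * sum(axis * v) * (1 - ca)
  }))
}

#' Simulate a rigid multi-pose landmark series
#'
#' Rotates the mandible landmarks of an apparatus rigidly about a known
#' axis through the joint centre, pose by pose, translates the apodeme
#' centre of mass along the apodeme main axis by the model displacement,
#' and optionally adds isotropic Gaussian landmark noise. The output uses
#' the raw landmark table dialect consumed by [normalize_landmarks()].
#'
#' @param angles opening angles (degrees) of the poses; at least 2,
#'   distinct.
#' @param axis rotation axis (default the apparatus' axis).
#' @param noise isotropic landmark noise level: the root-mean-square
#'   displacement of each landmark is `noise` times its distance from the
#'   joint centre (per-component standard deviation `noise * |v| / sqrt(3)`;
#'   default 0).
#' @param seed integer seed; required when `noise > 0`.
#' @param apparatus the apparatus providing the base geometry (default
#'   [make_reference_apparatus()]).
#' @param head_length head length in mm (default 3.5).
#' @param hemisphere `"left"` or `"right"`.
#' @return A list with `landmarks` (data frame: `pose`, `hemisphere`,
#'   `landmark`, `x`, `y`, `z`) and `truth` (list with the rotation `axis`,
#'   `angles` and `head_length`).
#' @export
make_pose_series <- function(angles, axis = NULL, noise = 0, seed = NULL,
                             apparatus = make_reference_apparatus(),
                             head_length = 3.5,
                             hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (length(angles) < 2L) bm_stop("need at least 2 pose angles")
  if (anyDuplicated(angles)) bm_stop("pose angles must be distinct")
  if (noise > 0) {
    if (is.null(seed)) bm_stop("'seed' is required when noise > 0")
    set.seed(as.integer(seed))
  }
  if (is.null(axis)) axis <- apparatus$frame$axis
  axis <- unit_vec(check_vec3(axis, "axis"), "axis")
  jc <- c(10, 5, 2)   # arbitrary scan origin offset, mm
  lv <- apparatus$levers
  mand0 <- rbind(inlever = lv$inlever,
                 outlever_distal = lv$outlever_distal,
                 outlever_proximal = lv$outlever_proximal)
  com0 <- lv$inlever + 0.9 * lv$apodeme_axis  # apodeme body anterior of its attachment
  rows <- lapply(seq_along(angles), function(i) {
    th <- angles[i]
    rot <- rotate_about(mand0, axis, deg2rad(th - lv$theta0_deg))
    delta <- apodeme_displacement(th, lv, apparatus$frame)$delta
    com <- com0 - delta * lv$apodeme_axis
    pts <- rbind(joint_centre = c(0, 0, 0),
                 head_rear = c(-head_length, 0, 0),
                 rot,
                 apodeme_com = com)
    if (noise > 0) {
      nm <- rownames(pts)
      scale <- noise * sqrt(rowSums(pts^2)) / sqrt(3)
      pts <- pts + matrix(rnorm(length(pts)), ncol = 3) * scale
      rownames(pts) <- nm
    }
    pts <- sweep(pts, 2, -jc)  # translate into the scan frame
    if (hemisphere == "right") pts[, 2] <- -pts[, 2]
    data.frame(pose = sprintf("pose_%02d", i), hemisphere = hemisphere,
               landmark = rownames(pts), x = pts[, 1], y = pts[, 2],
               z = pts[, 3], row.names = NULL)
  })
  list(landmarks = do.call(rbind, rows),
       truth = list(axis = axis, angles = angles, head_length = head_length))
}

#' Simulate a pennate fibre field with ground truth
#'
#' Builds a non-crossing pennate fan: apodeme surface points spaced along
#' the anterior-posterior (x) axis, each seed displaced from its insertion
#' by the fibre's total length at a common pennation angle. When
#' `filament_mm > 0` (or `build_mask = TRUE`) a muscle mask is generated in
#' which a muscle-free corridor of width `filament_mm` (measured along the
#' fibre direction) separates the apodeme from the muscle tissue, so that
#' grown filaments have known length.
#'
#' @param n number of fibres (default 100).
#' @param phi_deg common pennation angle, degrees (default 30).
#' @param total_length_range range of total fibre lengths in mm (default
#'   `c(1.5, 2.0)`).
#' @param filament_mm nominal filament length in mm (default 0: direct
#'   attachment everywhere).
#' @param voxel_size voxel edge length in mm (default 0.02).
#' @param seed integer seed for the length jitter.
#' @param build_mask force mask generation even when `filament_mm = 0`.
#' @return A list with `field` (a [fibre_field()]) and `truth` (tibble with
#'   per-fibre `seed`, `insertion`, `total_length_mm`, `filament_mm`,
#'   `pennation_deg`).
#' @export
make_fibre_field <- function(n = 100, phi_deg = 30,
                             total_length_range = c(1.5, 2.0),
                             filament_mm = 0, voxel_size = 0.02, seed,
                             build_mask = filament_mm > 0) {
  if (missing(seed)) bm_stop("'seed' is required")
  set.seed(as.integer(seed))
  phi <- deg2rad(phi_deg)
  spacing_px <- 3
  margin_px <- 10
  lt_px <- sort(runif(n, total_length_range[1], total_length_range[2]),
                decreasing = TRUE) / voxel_size
  # anterior-most seeds get the longest fibres: with spacing 3 px the seed
  # x-order then matches the insertion x-order (non-crossing fan)
  ins_x <- margin_px + spacing_px * (seq_len(n) - 1)
  ins <- cbind(ins_x, margin_px, margin_px)
  seeds <- ins + cbind(lt_px * cos(phi), lt_px * sin(phi), 0)
  mask <- NULL
  if (build_mask || filament_mm > 0) {
    # corridor width along the fibre direction: muscle starts at
    # y >= insertion_y + filament_px * sin(phi)
    y_muscle <- margin_px + filament_mm / voxel_size * sin(phi)
    dims <- c(ceiling(max(seeds[, 1]) + margin_px),
              ceiling(max(seeds[, 2]) + margin_px),
              2 * margin_px)
    mask <- array(FALSE, dim = dims)
    ys <- seq_len(dims[2])
    mask[, ys > y_muscle, ] <- TRUE
  }
  field <- fibre_field(seeds = seeds, apodeme_surface = ins,
                       apodeme_axis = c(1, 0, 0), voxel_size = voxel_size,
                       muscle_mask = mask)
  truth <- tibble::tibble(
    seed = seq_len(n), insertion = seq_len(n),
    total_length_mm = lt_px * voxel_size,
    filament_mm = filament_mm,
    pennation_deg = phi_deg
  )
  list(field = field, truth = truth)
}
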