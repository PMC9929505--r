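# Lever-arm and joint kinematics of the mandible: apodeme angle, effective
# levers, mechanical advantage, apodeme displacement and gape.

#' Mandible joint frame
#'
#' A joint frame consists of a reference point on the rotation axis (the
#' joint centre, typically the ventral condyle) and the unit rotation axis
#' itself. The choice of reference point along the axis does not affect any
#' moment-arm calculation; it anchors the lever vectors.
#'
#' @param centre numeric 3-vector, joint centre position (mm).
#' @param axis numeric 3-vector, rotation axis; normalized internally.
#' @param dv_axis optional numeric 3-vector giving the dorso-ventral head
#'   axis. When supplied, the sign of the rotation axis is flipped if needed
#'   so that `axis . dv_axis >= 0`, making the apodeme and opening angles
#'   single-valued.
#' @return An object of class `joint_frame` with fields `centre` and `axis`
#'   (unit vector).
#' @examples
#' joint_frame(c(0, 0, 0), c(0, 0, 2))  # axis is normalized
#' @export
joint_frame <- function(centre, axis, dv_axis = NULL) {
  centre <- check_vec3(centre, "centre")
  axis <- unit_vec(check_vec3(axis, "axis"), "axis")
  if (!is.null(dv_axis)) {
    dv_axis <- check_vec3(dv_axis, "dv_axis")
    if (sum(axis * dv_axis) < 0) axis <- -axis
  }
  structure(list(centre = centre, axis = axis), class = "joint_frame")
}

#' @export
print.joint_frame <- function(x, ...) {
  cat("Joint frame\n")
  cat("  centre (mm):", format(x$centre, digits = 4), "\n")
  cat("  axis       :", format(x$axis, digits = 4), "\n")
  invisible(x)
}

#' Mandible lever set
#'
#' Lever vectors from the joint centre together with the apodeme main axis
#' and the reference angles at which they were measured. The opening angle
#' theta is measured between the lateral head axis and the projection of the
#' outlever onto the rotation plane; the apodeme angle gamma between the
#' projections of inlever and apodeme main axis. Both reference angles refer
#' to the same (arbitrary) reference pose.
#'
#' @param inlever numeric 3-vector, joint centre to apodeme attachment (mm).
#' @param outlever_distal numeric 3-vector, joint centre to the most distal
#'   tooth tip (mm).
#' @param apodeme_axis numeric 3-vector, apodeme main axis; normalized.
#' @param gamma0_deg apodeme angle at the reference pose, degrees, in
#'   (0, 180).
#' @param theta0_deg opening angle at the reference pose, degrees.
#' @param outlever_proximal optional numeric 3-vector, joint centre to the
#'   most proximal tooth tip (mm); used for axis estimation, not for the
#'   mechanical advantage.
#' @return An object of class `lever_set`.
#' @export
lever_set <- function(inlever, outlever_distal, apodeme_axis, gamma0_deg,
                      theta0_deg, outlever_proximal = NULL) {
  inlever <- check_vec3(inlever, "inlever")
  outlever_distal <- check_vec3(outlever_distal, "outlever_distal")
  apodeme_axis <- unit_vec(check_vec3(apodeme_axis, "apodeme_axis"),
                           "apodeme_axis")
  gamma0_deg <- check_scalar(gamma0_deg, "gamma0_deg")
  theta0_deg <- check_scalar(theta0_deg, "theta0_deg")
  if (gamma0_deg <= 0 || gamma0_deg >= 180) {
    bm_stop(sprintf("'gamma0_deg' must lie in (0, 180) degrees (got %g)",
                    gamma0_deg))
  }
  if (!is.null(outlever_proximal)) {
    outlever_proximal <- check_vec3(outlever_proximal, "outlever_proximal")
  }
  structure(list(
    inlever = inlever,
    outlever_distal = outlever_distal,
    outlever_proximal = outlever_proximal,
    apodeme_axis = apodeme_axis,
    gamma0_deg = gamma0_deg,
    theta0_deg = theta0_deg
  ), class = "lever_set")
}

#' Apodeme angle at a given opening angle
#'
#' The apodeme angle gamma between the projections of the inlever and the
#' apodeme main axis onto the rotation plane varies linearly with the opening
#' angle: `gamma(theta) = theta0 - theta + gamma0`. Values outside (0, 180)
#' degrees indicate a geometrically degenerate configuration and are returned
#' unchanged for the caller to interpret.
#'
#' @param theta_deg opening angle(s), degrees; vectorized.
#' @param levers a [lever_set()].
#' @return Apodeme angle(s) in degrees.
#' @examples
#' lv <- lever_set(c(0, 1, 0), c(2, 0, 0), c(1, 0, 0), 90, 51)
#' apodeme_angle(51, lv)   # 90 at the reference pose
#' apodeme_angle(105, lv)  # 36
#' @export
apodeme_angle <- function(theta_deg, levers) {
  stopifnot(inherits(levers, "lever_set"))
  levers$theta0_deg - theta_deg + levers$gamma0_deg
}

#' Effective levers and mechanical advantage
#'
#' The effective outlever is the projection length of the distal outlever
#' onto the rotation plane, `|R x Lo|`, and is independent of the opening
#' angle because the bite force is perpendicular to the outlever by
#' definition. The effective inlever is
#' `sin(gamma(theta)) * |R x Li| * |R x A|`: the projected inlever, reduced
#' by the apodeme angle and by the out-of-plane misalignment of the apodeme
#' force. The mechanical advantage is their ratio and is maximal where
#' `gamma(theta) = 90` degrees.
#'
#' @inheritParams apodeme_angle
#' @param frame a [joint_frame()].
#' @return A [tibble::tibble] with columns `theta_deg`, `gamma_deg`,
#'   `inlever_eff`, `outlever_eff` (mm) and `mechanical_advantage`.
#' @export
effective_levers <- function(theta_deg, levers, frame) {
  stopifnot(inherits(levers, "lever_set"), inherits(frame, "joint_frame"))
  r <- frame$axis
  proj_in <- projection_length(r, levers$inlever)
  proj_out <- projection_length(r, levers$outlever_distal)
  proj_apo <- projection_length(r, levers$apodeme_axis)
  if (proj_out < PROJECTION_TOL) {
    bm_stop("outlever projection |R x Lo| is degenerate (parallel to the rotation axis)",
            class = "bitemech_degenerate_error")
  }
  if (proj_in < PROJECTION_TOL || proj_apo < PROJECTION_TOL) {
    bm_stop("inlever or apodeme-axis projection onto the rotation plane is degenerate",
            class = "bitemech_degenerate_error")
  }
  gamma <- apodeme_angle(theta_deg, levers)
  in_eff <- sin(deg2rad(gamma)) * proj_in * proj_apo
  tibble::tibble(
    theta_deg = theta_deg,
    gamma_deg = gamma,
    inlever_eff = in_eff,
    outlever_eff = proj_out,
    mechanical_advantage = in_eff / proj_out
  )
}

#' Apodeme displacement
#'
#' Displacement of the apodeme along its main axis as the mandible rotates
#' away from the reference pose:
#' `Delta(theta) = [cos(gamma0) - cos(gamma(theta))] * |R x Li| * |R x A|`,
#' with `Delta(theta0) = 0`, increasing as the mandible closes. The
#' `longitudinal` and `lateral` columns are the components of the apodeme
#' attachment-point path in the rotation plane, parallel and perpendicular to
#' the projected apodeme main axis (the lateral component is accommodated by
#' the apodeme ligament, not by apodeme translation).
#'
#' @inheritParams effective_levers
#' @return A [tibble::tibble] with columns `theta_deg`, `delta`,
#'   `longitudinal`, `lateral` (all mm).
#' @export
apodeme_displacement <- function(theta_deg, levers, frame) {
  stopifnot(inherits(levers, "lever_set"), inherits(frame, "joint_frame"))
  r <- frame$axis
  proj_in <- projection_length(r, levers$inlever)
  proj_apo <- projection_length(r, levers$apodeme_axis)
  gamma <- deg2rad(apodeme_angle(theta_deg, levers))
  gamma0 <- deg2rad(levers$gamma0_deg)
  longitudinal <- (cos(gamma0) - cos(gamma)) * proj_in
  lateral <- (sin(gamma) - sin(gamma0)) * proj_in
  tibble::tibble(
    theta_deg = theta_deg,
    delta = longitudinal * proj_apo,
    longitudinal = longitudinal,
    lateral = lateral
  )
}

#' Mandible gape
#'
#' Twice the signed shortest distance between the distal tooth tip and the
#' sagittal plane; negative when the mandibles overlap (the tip has crossed
#' the plane against the plane normal).
#'
#' @param tooth_tip numeric 3-vector, distal tooth tip position (mm).
#' @param plane_point numeric 3-vector, any point on the sagittal plane (mm).
#' @param plane_normal numeric 3-vector, unit normal of the sagittal plane,
#'   oriented towards the mandible's side of the head.
#' @return Gape in mm (signed).
#' @examples
#' gape(c(0, 1.8, 0), c(0, 0, 0), c(0, 1, 0))  # 3.6
#' @export
gape <- function(tooth_tip, plane_point, plane_normal) {
  tooth_tip <- check_vec3(tooth_tip, "tooth_tip")
  plane_point <- check_vec3(plane_point, "plane_point")
  plane_normal <- check_vec3(plane_normal, "plane_normal")
  if (abs(vec_norm(plane_normal) - 1) > 1e-6) {
    bm_stop("'plane_normal' must be a unit vector")
  }
  2 * sum((tooth_tip - plane_point) * plane_normal)
}
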