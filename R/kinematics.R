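# Estimation of the mandible rotation axis from multi-pose landmarks and of
# the apodeme displacement axis from centre-of-mass coordinates.
#
# Landmark frame convention: x = anterior(+)/posterior(-), y = lateral
# (positive towards the left hemisphere), z = dorsal(+). The sagittal plane
# of the normalized frame is y = 0.

LANDMARK_NAMES <- c("joint_centre", "head_rear", "inlever", "outlever_distal",
                    "outlever_proximal", "apodeme_com")

#' Normalize multi-pose landmarks into a common head frame
#'
#' Per pose: the origin is moved to the joint centre, all coordinates are
#' divided by head length (the anterior-posterior distance between the
#' mandible joint and the rear of the head capsule), and right-hemisphere
#' poses are mirrored across the sagittal plane (lateral coordinate
#' negated) so that both hemispheres share one frame.
#'
#' @param landmarks a data frame with columns `pose`, `hemisphere`
#'   (`"left"` or `"right"`), `landmark`, `x`, `y`, `z` (mm). Required
#'   landmarks per pose: `joint_centre`, `head_rear`, `inlever`,
#'   `outlever_distal`, `outlever_proximal`; `apodeme_com` is optional.
#' @return A list of `pose_landmarks` objects, each with fields `pose_id`,
#'   `hemisphere`, `head_length` (mm), `vectors` (named list of unit-free
#'   normalized 3-vectors from the joint centre) and `apodeme_com` (or
#'   `NULL`).
#' @export
normalize_landmarks <- function(landmarks) {
  need <- c("pose", "hemisphere", "landmark", "x", "y", "z")
  if (!is.data.frame(landmarks) || !all(need %in% names(landmarks))) {
    bm_stop(sprintf("'landmarks' must have columns %s",
                    paste(need, collapse = ", ")))
  }
  lapply(split(landmarks, landmarks$pose), function(df) {
    pose_id <- df$pose[1]
    hemi <- tolower(as.character(df$hemisphere[1]))
    if (!hemi %in% c("left", "right")) {
      bm_stop(sprintf("pose '%s': hemisphere must be 'left' or 'right'", pose_id))
    }
    get_lm <- function(name, required = TRUE) {
      row <- df[df$landmark == name, , drop = FALSE]
      if (nrow(row) < 1L) {
        if (required) {
          bm_stop(sprintf("pose '%s': missing landmark '%s'", pose_id, name))
        }
        return(NULL)
      }
      as.numeric(row[1, c("x", "y", "z")])
    }
    jc <- get_lm("joint_centre")
    rear <- get_lm("head_rear")
    head_length <- abs(jc[1] - rear[1])
    if (head_length <= 0) {
      bm_stop(sprintf("pose '%s': zero head length between joint and head rear", pose_id))
    }
    norm1 <- function(v) {
      if (is.null(v)) return(NULL)
      v <- (v - jc) / head_length
      if (hemi == "right") v[2] <- -v[2]
      v
    }
    structure(list(
      pose_id = pose_id,
      hemisphere = hemi,
      head_length = head_length,
      vectors = list(
        inlever = norm1(get_lm("inlever")),
        outlever_distal = norm1(get_lm("outlever_distal")),
        outlever_proximal = norm1(get_lm("outlever_proximal"))
      ),
      apodeme_com = norm1(get_lm("apodeme_com", required = FALSE))
    ), class = "pose_landmarks")
  })
}

# objective: sum over mandible vectors v of the squared deviation of the
# angle(axis, v_pose) from its per-vector mean across poses (degrees^2)
axis_objective <- function(axis, unit_mats) {
  total <- 0
  for (m in unit_mats) {
    ang <- rad2deg(acos(pmin(1, pmax(-1, as.numeric(m %*% axis)))))
    total <- total + sum((ang - mean(ang))^2)
  }
  total
}

sph_to_vec <- function(p) {
  c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
}

# 26 lattice start directions: the non-zero points of {-1,0,1}^3
lattice_starts <- function() {
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  g <- g[rowSums(abs(g)) > 0, ]
  t(apply(g, 1, function(v) v / sqrt(sum(v^2))))
}

#' Estimate the mandible rotation axis from multi-pose landmarks
#'
#' If the mandible rotates about a single fixed axis, the angle between that
#' axis and any vector connecting two points on the mandible is constant
#' across poses. The axis is found by minimizing the squared angular
#' residuals of the inlever and the distal and proximal outlevers around
#' their per-vector means, over the unit sphere (azimuth/elevation
#' parametrization, derivative-free Nelder-Mead from 26 lattice starts).
#'
#' @param poses a list of `pose_landmarks` from [normalize_landmarks()];
#'   at least 2 poses at distinct opening angles.
#' @param dv_axis dorso-ventral axis used to fix the sign of the estimate
#'   (default `c(0, 0, 1)` in the normalized frame).
#' @return An object of class `axis_estimate` with fields `axis` (unit
#'   3-vector), `residual` (mean squared angular deviation, degrees^2),
#'   `n_poses` and `per_vector_angles` (matrix of angles, degrees).
#' @export
estimate_rotation_axis <- function(poses, dv_axis = c(0, 0, 1)) {
  if (!is.list(poses) || length(poses) < 2L ||
      !all(vapply(poses, inherits, logical(1), "pose_landmarks"))) {
    bm_stop("'poses' must be a list of >= 2 pose_landmarks objects")
  }
  vec_names <- c("inlever", "outlever_distal", "outlever_proximal")
  unit_mats <- lapply(vec_names, function(nm) {
    m <- t(vapply(poses, function(p) {
      v <- p$vectors[[nm]]
      if (is.null(v)) bm_stop(sprintf("pose '%s' lacks vector '%s'", p$pose_id, nm))
      v / vec_norm(v)
    }, numeric(3)))
    m
  })
  spread <- max(vapply(unit_mats, function(m) {
    max(apply(m, 2, function(col) diff(range(col))))
  }, numeric(1)))
  if (spread < 1e-9) {
    bm_stop("all poses are identical; the rotation axis is unidentifiable",
            class = "bitemech_degenerate_error")
  }

  starts <- lattice_starts()
  best_par <- NULL
  best_val <- Inf
  for (i in seq_len(nrow(starts))) {
    v0 <- starts[i, ]
    p0 <- c(atan2(v0[2], v0[1]), asin(pmin(1, pmax(-1, v0[3]))))
    opt <- optim(p0, function(p) axis_objective(sph_to_vec(p), unit_mats),
                 method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
    if (opt$value < best_val) {
      best_val <- opt$value
      best_par <- opt$par
    }
  }
  axis <- sph_to_vec(best_par)
  if (sum(axis * dv_axis) < 0) axis <- -axis
  angles <- vapply(unit_mats, function(m) {
    rad2deg(acos(pmin(1, pmax(-1, as.numeric(m %*% axis)))))
  }, numeric(length(poses)))
  if (is.null(dim(angles))) angles <- matrix(angles, nrow = length(poses))
  colnames(angles) <- vec_names
  structure(list(
    axis = axis,
    residual = best_val / (length(vec_names) * length(poses)),
    n_poses = length(poses),
    per_vector_angles = angles
  ), class = "axis_estimate")
}

#' @export
print.axis_estimate <- function(x, ...) {
  cat(sprintf("Rotation-axis estimate from %d poses\n", x$n_poses))
  cat("  axis    :", format(x$axis, digits = 5), "\n")
  cat(sprintf("  residual: %.4g deg^2 (mean squared angular deviation)\n", x$residual))
  invisible(x)
}

#' Apodeme displacement axis from centre-of-mass coordinates
#'
#' A principal component analysis of the normalized apodeme
#' centre-of-mass coordinates across poses. The first principal direction
#' is the displacement axis; the fraction of variance it explains measures
#' how linear the displacement path is. Displacements are the signed
#' positions along this axis, centred on their mean and rescaled to mm with
#' the average head length.
#'
#' @param coms a numeric matrix or data frame (n poses x 3) of normalized
#'   apodeme centre-of-mass coordinates; at least 3 poses.
#' @param mean_head_length average head length in mm used to rescale the
#'   normalized displacements.
#' @param apodeme_axis optional unit 3-vector; when supplied, the angle
#'   between the recovered displacement axis and this apodeme main axis is
#'   reported in the result.
#' @return A list with `axis` (unit 3-vector, oriented towards positive
#'   anterior-posterior displacement), `r2` (variance fraction explained by
#'   the first component), `displacements` (mm, centred on their mean) and
#'   `apodeme_angle_deg` (degrees, or `NA` when no axis was supplied).
#' @export
displacement_axis <- function(coms, mean_head_length, apodeme_axis = NULL) {
  coms <- as.matrix(coms)
  if (!is.numeric(coms) || ncol(coms) != 3L) {
    bm_stop("'coms' must be an n x 3 numeric matrix")
  }
  if (nrow(coms) < 3L) bm_stop("need >= 3 poses for the displacement axis")
  mean_head_length <- check_scalar(mean_head_length, "mean_head_length",
                                   positive = TRUE)
  sds <- apply(coms, 2, sd)
  if (all(sds < 1e-12)) {
    warning("centre-of-mass coordinates are coincident; displacement axis is rank-deficient",
            call. = FALSE)
  }
  pc <- prcomp(coms, center = TRUE, scale. = FALSE)
  axis <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  # orient the axis so that displacement increases towards posterior (-x)
  if (axis[1] > 0) {
    axis <- -axis
    scores <- -scores
  }
  disp <- (scores - mean(scores)) * mean_head_length
  ang <- NA_real_
  if (!is.null(apodeme_axis)) {
    apodeme_axis <- check_vec3(apodeme_axis, "apodeme_axis")
    ang <- vec_angle_deg(axis, apodeme_axis)
    ang <- min(ang, 180 - ang)  # axis direction is sign-free
  }
  list(
    axis = as.numeric(axis),
    r2 = pc$sdev[1]^2 / sum(pc$sdev^2),
    displacements = as.numeric(disp),
    apodeme_angle_deg = ang
  )
}
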