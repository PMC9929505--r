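# Reading and writing the package's file dialects: JSON apparatus configs,
# CSV measurement/landmark/point tables, TIFF mask stacks. All CSV files are
# comma-separated, UTF-8, '.' decimal, header mandatory.

APPARATUS_SCHEMA <- "bitemech-apparatus/1"

#' Read a bite-apparatus configuration from JSON
#'
#' The configuration holds the joint frame, lever vectors (mm), reference
#' angles (degrees) and the muscle block (volume, fibre populations,
#' physiology). All invariants are checked at load time; a configuration
#' declaring a non-degree `angle_unit` is rejected.
#'
#' @param path path to a JSON file written by [write_apparatus()] or by
#'   hand.
#' @return A [bite_apparatus()].
#' @export
read_apparatus <- function(path) {
  if (!file.exists(path)) bm_stop(sprintf("apparatus config not found: %s", path))
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$angle_unit) && !identical(tolower(cfg$angle_unit), "degrees")) {
    bm_stop(sprintf(
      "apparatus config declares angle_unit '%s'; this package reads degrees only -- convert the config",
      cfg$angle_unit))
  }
  need <- c("joint_centre", "rotation_axis", "inlever", "outlever_distal",
            "apodeme_axis", "gamma0_deg", "theta0_deg", "muscle")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    bm_stop(sprintf("apparatus config missing keys: %s", paste(miss, collapse = ", ")))
  }
  mus <- cfg$muscle
  for (k in c("volume_mm3", "populations", "physiology")) {
    if (is.null(mus[[k]])) bm_stop(sprintf("muscle block missing key '%s'", k))
  }
  pops_df <- as.data.frame(mus$populations)
  pops <- lapply(seq_len(nrow(pops_df)), function(i) {
    fibre_population(
      phi0_deg = pops_df$phi0_deg[i],
      fibre_length0 = pops_df$fibre_length0_mm[i],
      filament_length = if ("filament_length_mm" %in% names(pops_df))
        pops_df$filament_length_mm[i] else 0,
      number_fraction = pops_df$number_fraction[i]
    )
  })
  phys <- mus$physiology
  bite_apparatus(
    frame = joint_frame(cfg$joint_centre, cfg$rotation_axis),
    levers = lever_set(cfg$inlever, cfg$outlever_distal, cfg$apodeme_axis,
                       cfg$gamma0_deg, cfg$theta0_deg,
                       outlever_proximal = cfg$outlever_proximal),
    muscle = muscle_architecture(mus$volume_mm3, pops,
                                 reference = if (is.null(mus$reference)) 1L
                                 else mus$reference),
    physiology = force_length_params(phys$sigma_max_MPa, phys$L_opt_mm,
                                     phys$beta),
    theta_range = if (is.null(cfg$theta_range)) c(35, 105) else cfg$theta_range,
    pooled_area = if (is.null(cfg$pooled_area)) TRUE else cfg$pooled_area
  )
}

#' Write a bite apparatus to JSON
#'
#' @param apparatus a [bite_apparatus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_apparatus <- function(apparatus, path) {
  stopifnot(inherits(apparatus, "bite_apparatus"))
  lv <- apparatus$levers
  mus <- apparatus$muscle
  phys <- apparatus$physiology
  cfg <- list(
    schema = APPARATUS_SCHEMA,
    angle_unit = "degrees",
    joint_centre = apparatus$frame$centre,
    rotation_axis = apparatus$frame$axis,
    inlever = lv$inlever,
    outlever_distal = lv$outlever_distal,
    outlever_proximal = lv$outlever_proximal,
    apodeme_axis = lv$apodeme_axis,
    gamma0_deg = lv$gamma0_deg,
    theta0_deg = lv$theta0_deg,
    theta_range = apparatus$theta_range,
    pooled_area = apparatus$pooled_area,
    muscle = list(
      volume_mm3 = mus$volume,
      reference = mus$reference,
      populations = lapply(mus$populations, function(p) list(
        phi0_deg = p$phi0_deg,
        fibre_length0_mm = p$fibre_length0,
        filament_length_mm = p$filament_length,
        number_fraction = p$number_fraction
      )),
      physiology = list(sigma_max_MPa = phys$sigma_max,
                        L_opt_mm = phys$l_opt,
                        beta = phys$beta)
    )
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read bite-force measurements from CSV
#'
#' Required columns: `theta_deg`, `force_measured_N`. Optional columns:
#' `cos_alpha`, `plate_moment_cal_mm`, `plate_moment_bite_mm`, `contact`,
#' and the sensor geometry vectors `outlever_{x,y,z}`,
#' `sensor_{x,y,z}`. Rows violating invariants (negative force,
#' non-positive plate moments) are reported with their row number.
#'
#' @param path path to a CSV file.
#' @return A [tibble::tibble].
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) bm_stop(sprintf("measurement file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("theta_deg", "force_measured_N")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    bm_stop(sprintf("measurement file missing columns: %s",
                    paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(df$force_measured_N) | df$force_measured_N < 0)
  if (length(bad)) {
    bm_stop(sprintf("negative or non-finite measured force in row(s) %s",
                    paste(head(bad, 5), collapse = ", ")))
  }
  for (cc in c("plate_moment_cal_mm", "plate_moment_bite_mm")) {
    if (cc %in% names(df)) {
      bad <- which(!is.finite(df[[cc]]) | df[[cc]] <= 0)
      if (length(bad)) {
        bm_stop(sprintf("non-positive %s in row(s) %s", cc,
                        paste(head(bad, 5), collapse = ", ")))
      }
    }
  }
  tibble::as_tibble(df)
}

#' Correct a table of sensor measurements to bite forces
#'
#' Applies the one-dimensional sensor relation row by row. When the table
#' carries `cos_alpha` directly it is used as-is; otherwise the angle is
#' computed from the `outlever_*` and `sensor_*` vector columns and the
#' joint frame.
#'
#' @param measurements a tibble from [read_measurements()].
#' @param frame a [joint_frame()]; required when `cos_alpha` must be
#'   computed from vectors.
#' @param cos_alpha_floor passed to [measured_to_bite()].
#' @return The input with an added `force` column (bite force, N).
#' @export
correct_measurements <- function(measurements, frame = NULL,
                                 cos_alpha_floor = 0.2) {
  df <- measurements
  n <- nrow(df)
  gam <- if (all(c("plate_moment_cal_mm", "plate_moment_bite_mm") %in% names(df))) {
    df$plate_moment_cal_mm / df$plate_moment_bite_mm
  } else rep(1, n)
  if ("cos_alpha" %in% names(df)) {
    ca <- df$cos_alpha
    if (any(ca <= cos_alpha_floor)) {
      bm_stop(sprintf("cos_alpha at or below the floor %.3f in row(s) %s",
                      cos_alpha_floor,
                      paste(head(which(ca <= cos_alpha_floor), 5), collapse = ", ")))
    }
    df$force <- gam * df$force_measured_N / ca
    return(df)
  }
  vec_cols <- c(paste0("outlever_", c("x", "y", "z")),
                paste0("sensor_", c("x", "y", "z")))
  if (!all(vec_cols %in% names(df))) {
    bm_stop("need either a cos_alpha column or outlever_*/sensor_* vector columns")
  }
  if (is.null(frame)) bm_stop("'frame' is required to compute cos_alpha from vectors")
  df$force <- vapply(seq_len(n), function(i) {
    meas <- bite_measurement(
      theta_deg = df$theta_deg[i],
      force_measured = df$force_measured_N[i],
      outlever = as.numeric(df[i, vec_cols[1:3]]),
      sensor_axis = as.numeric(df[i, vec_cols[4:6]]),
      plate_moment_cal = if ("plate_moment_cal_mm" %in% names(df))
        df$plate_moment_cal_mm[i] else 1,
      plate_moment_bite = if ("plate_moment_bite_mm" %in% names(df))
        df$plate_moment_bite_mm[i] else 1
    )
    measured_to_bite(meas, frame, cos_alpha_floor)
  }, numeric(1))
  df
}

#' Read a raw landmark table from CSV
#'
#' Expected columns: `pose`, `hemisphere`, `landmark`, `x`, `y`, `z` (mm);
#' an `id` column is carried through when present.
#'
#' @param path path to a CSV file.
#' @return A [tibble::tibble].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) bm_stop(sprintf("landmark file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pose", "hemisphere", "landmark", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    bm_stop(sprintf("landmark file missing columns: %s",
                    paste(miss, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Read a 3-D point table (x, y, z) from CSV
#'
#' Used for fibre seeds, apodeme surface points and apodeme centres of
#' mass (voxel units or normalized coordinates, depending on context).
#'
#' @param path path to a CSV file with columns `x`, `y`, `z`.
#' @return A numeric matrix with 3 columns.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) bm_stop(sprintf("point file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "z") %in% names(df))) {
    bm_stop("point file must have columns x, y, z")
  }
  as.matrix(df[, c("x", "y", "z")])
}

#' Read a muscle mask from a TIFF stack
#'
#' One page per slice (third array dimension); non-binary intensities are
#' thresholded at > 0 with a warning.
#'
#' @param path path to a TIFF file.
#' @return A 3-D logical array ordered (x, y, slice).
#' @export
read_mask_tiff <- function(path) {
  if (!file.exists(path)) bm_stop(sprintf("mask file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    t(p)  # TIFF rows are y; store as (x, y)
  })
  arr <- array(unlist(slices), dim = c(dim(slices[[1]]), length(slices)))
  if (!all(arr %in% c(0, 1))) {
    warning("non-binary muscle mask thresholded at > 0", call. = FALSE)
  }
  arr > 0
}

#' Write a muscle mask as a TIFF stack
#'
#' @param mask a 3-D logical (or 0/1 numeric) array ordered (x, y, slice).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  if (length(dim(mask)) != 3L) bm_stop("'mask' must be a 3-D array")
  pages <- lapply(seq_len(dim(mask)[3]), function(k) {
    t(mask[, , k]) * 1
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}
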