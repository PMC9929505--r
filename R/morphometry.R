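# Micro-CT fibre morphometry: rank-matching of fibre seeds to apodeme
# surface points, filament growth through a muscle mask, attachment
# classification, and per-fibre length/pennation output.
#
# Voxel convention: point coordinates are continuous voxel units, 0-based;
# the centre of voxel (i, j, k) of the mask array (1-based R indices) is at
# (i - 0.5, j - 0.5, k - 0.5). Physical positions are voxel units times
# voxel_size (mm).

#' Fibre field
#'
#' Container for one muscle's morphometry inputs: fibre seed points on the
#' head capsule, candidate insertion points on the apodeme surface, the
#' apodeme main axis, an optional 3-D muscle mask and the scale parameters.
#'
#' @param seeds n x 3 matrix of fibre seed coordinates (voxel units).
#' @param apodeme_surface m x 3 matrix of apodeme surface point coordinates
#'   (voxel units).
#' @param apodeme_axis unit 3-vector, apodeme main axis (pennation is
#'   measured against it).
#' @param voxel_size voxel edge length in mm, > 0.
#' @param muscle_mask optional 3-D logical array (muscle tissue = `TRUE`);
#'   non-logical arrays are thresholded at > 0 with a warning.
#' @param anterior_axis unit 3-vector of the anterior-posterior sorting
#'   direction (default `c(1, 0, 0)`).
#' @param secondary_axis unit 3-vector used to break sorting ties (default
#'   dorso-ventral, `c(0, 0, 1)`).
#' @param fibre_diameter_px fibre diameter in pixels (default 5); sets both
#'   the filament classification threshold and the short-fibre exclusion.
#' @return An object of class `fibre_field`.
#' @export
fibre_field <- function(seeds, apodeme_surface, apodeme_axis, voxel_size,
                        muscle_mask = NULL, anterior_axis = c(1, 0, 0),
                        secondary_axis = c(0, 0, 1), fibre_diameter_px = 5) {
  seeds <- as.matrix(seeds)
  apodeme_surface <- as.matrix(apodeme_surface)
  if (!is.numeric(seeds) || ncol(seeds) != 3L || nrow(seeds) < 1L) {
    bm_stop("'seeds' must be a non-empty n x 3 numeric matrix")
  }
  if (!is.numeric(apodeme_surface) || ncol(apodeme_surface) != 3L ||
      nrow(apodeme_surface) < 1L) {
    bm_stop("'apodeme_surface' must be a non-empty m x 3 numeric matrix")
  }
  voxel_size <- check_scalar(voxel_size, "voxel_size", positive = TRUE)
  if (!is.null(muscle_mask)) {
    if (length(dim(muscle_mask)) != 3L) {
      bm_stop("'muscle_mask' must be a 3-D array")
    }
    if (!is.logical(muscle_mask)) {
      warning("non-binary muscle mask thresholded at > 0", call. = FALSE)
      muscle_mask <- muscle_mask > 0
    }
    pts <- rbind(seeds, apodeme_surface)
    if (any(pts < 0) || any(t(t(pts) - dim(muscle_mask)) > 0)) {
      bm_stop("mask dimensions do not cover all seed/surface points")
    }
  }
  structure(list(
    seeds = seeds,
    apodeme_surface = apodeme_surface,
    apodeme_axis = unit_vec(check_vec3(apodeme_axis, "apodeme_axis"), "apodeme_axis"),
    voxel_size = voxel_size,
    muscle_mask = muscle_mask,
    anterior_axis = unit_vec(check_vec3(anterior_axis, "anterior_axis"), "anterior_axis"),
    secondary_axis = unit_vec(check_vec3(secondary_axis, "secondary_axis"), "secondary_axis"),
    fibre_diameter_px = check_scalar(fibre_diameter_px, "fibre_diameter_px",
                                     positive = TRUE)
  ), class = "fibre_field")
}

#' Rank-match fibre seeds to apodeme surface points
#'
#' Fibre attachment density along the apodeme is approximately constant and
#' fibres rarely cross, so a seed's insertion can be found by sorting both
#' seeds and surface points along the anterior-posterior axis and matching
#' equal relative ranks: seed rank `i` of `N_s` is assigned the surface-rank
#' bin `((i-1) N_a / N_s, i N_a / N_s]`, and within that bin the surface
#' point closest in Euclidean distance is chosen (this prevents fibres from
#' crossing the apodeme). Empty bins fall back to the nearest non-empty
#' adjacent bin; with fewer surface points than seeds, shared insertions are
#' counted in the `multiplicity` attribute.
#'
#' @param field a [fibre_field()].
#' @return A [tibble::tibble] with columns `seed` (row index into
#'   `field$seeds`), `insertion` (row index into `field$apodeme_surface`)
#'   and `connection_px` (Euclidean seed-insertion distance, voxel units).
#'   Attributes: `fallbacks` (number of empty-bin fallbacks) and
#'   `multiplicity` (maximum number of seeds sharing one insertion).
#' @export
rank_match <- function(field) {
  stopifnot(inherits(field, "fibre_field"))
  ns <- nrow(field$seeds)
  na <- nrow(field$apodeme_surface)
  skey1 <- field$seeds %*% field$anterior_axis
  skey2 <- field$seeds %*% field$secondary_axis
  akey1 <- field$apodeme_surface %*% field$anterior_axis
  akey2 <- field$apodeme_surface %*% field$secondary_axis
  seed_order <- order(skey1, skey2)
  surf_order <- order(akey1, akey2)
  edges <- round(seq(0, na, length.out = ns + 1L))
  fallbacks <- 0L
  insertion <- integer(ns)
  for (i in seq_len(ns)) {
    lo <- edges[i] + 1L
    hi <- edges[i + 1L]
    if (hi < lo) {  # empty bin: nearest adjacent surface rank
      fallbacks <- fallbacks + 1L
      r <- min(max(edges[i], 1L), na)
      bin <- r
    } else {
      bin <- lo:hi
    }
    cand <- surf_order[bin]
    seed_idx <- seed_order[i]
    d2 <- rowSums((field$apodeme_surface[cand, , drop = FALSE] -
                     matrix(field$seeds[seed_idx, ], nrow = length(cand),
                            ncol = 3L, byrow = TRUE))^2)
    insertion[seed_idx] <- cand[which.min(d2)]
  }
  conn <- sqrt(rowSums((field$seeds -
                          field$apodeme_surface[insertion, , drop = FALSE])^2))
  out <- tibble::tibble(seed = seq_len(ns), insertion = insertion,
                        connection_px = conn)
  attr(out, "fallbacks") <- fallbacks
  attr(out, "multiplicity") <- max(table(insertion))
  if (na < ns) {
    message(sprintf("fewer surface points (%d) than seeds (%d): insertions shared up to %d times",
                    na, ns, attr(out, "multiplicity")))
  }
  out
}

#' Grow a filament from an apodeme insertion point through a muscle mask
#'
#' A ray is marched from the insertion point along the fibre orientation in
#' 0.5-voxel steps; each step the voxel under the ray is looked up in the
#' muscle mask and distinct muscle voxels are counted cumulatively. Growth
#' terminates once the count reaches `threshold_px` (about one fibre
#' diameter). The filament length is the non-muscle arc length travelled
#' before termination: the terminal dip into muscle tissue that triggers
#' the stop is not part of the filament. If the ray leaves the mask before
#' the threshold is reached, the filament is unreliable and the full
#' seed-insertion distance is returned instead.
#'
#' @param insertion numeric 3-vector, insertion point (voxel units).
#' @param direction numeric 3-vector pointing from the insertion towards
#'   the seed; normalized internally.
#' @param mask 3-D logical array of muscle tissue.
#' @param voxel_size voxel edge length (mm).
#' @param threshold_px number of muscle voxels to cross before terminating
#'   (default 5).
#' @param step_px step length in voxel units (default 0.5).
#' @param fallback_px length (voxel units) reported when the ray exits the
#'   mask, typically the full seed-insertion distance.
#' @return A list with `length_mm`, `length_px` and `reliable` (`FALSE`
#'   when the ray left the mask before crossing `threshold_px` muscle
#'   voxels).
#' @export
grow_filament <- function(insertion, direction, mask, voxel_size,
                          threshold_px = 5, step_px = 0.5,
                          fallback_px = NA_real_) {
  insertion <- check_vec3(insertion, "insertion")
  direction <- unit_vec(check_vec3(direction, "direction"), "direction")
  if (length(dim(mask)) != 3L) bm_stop("'mask' must be a 3-D array")
  voxel_size <- check_scalar(voxel_size, "voxel_size", positive = TRUE)
  dims <- dim(mask)
  n_muscle <- 0L
  prev_idx <- c(0L, 0L, 0L)
  pos <- insertion
  gap_px <- 0       # non-muscle arc length: the filament proper
  max_steps <- ceiling(sum(dims) / step_px) + 2L
  for (s in seq_len(max_steps)) {
    idx <- floor(pos) + 1L
    if (any(idx < 1L) || any(idx > dims)) {
      len_px <- if (is.na(fallback_px)) gap_px else fallback_px
      return(list(length_mm = len_px * voxel_size, length_px = len_px,
                  reliable = FALSE))
    }
    in_muscle <- isTRUE(mask[idx[1], idx[2], idx[3]])
    # a straight ray never revisits a voxel, so a changed index is a new one
    if (in_muscle && any(idx != prev_idx)) n_muscle <- n_muscle + 1L
    prev_idx <- idx
    if (n_muscle >= threshold_px) {
      return(list(length_mm = gap_px * voxel_size, length_px = gap_px,
                  reliable = TRUE))
    }
    if (!in_muscle) gap_px <- gap_px + step_px
    pos <- pos + step_px * direction
  }
  len_px <- if (is.na(fallback_px)) gap_px else fallback_px
  list(length_mm = len_px * voxel_size, length_px = len_px, reliable = FALSE)
}

#' Measure and classify muscle fibres
#'
#' Combines rank-matched seed-insertion pairs with filament growth into
#' per-fibre records: total length `L_t` (seed-insertion distance),
#' filament length `L_fil` (0 without a mask), fibre length
#' `L = L_t - L_fil`, pennation angle (between the seed-insertion line and
#' the apodeme main axis), and attachment class. Fibres with
#' `L_fil < fibre_diameter_px` voxels are classified as directly attached
#' (their filament length is set to 0 and `L = L_t`); fibres shorter than
#' twice the fibre diameter are excluded with a reason.
#'
#' @param field a [fibre_field()].
#' @param pairs optional result of [rank_match()]; computed when missing.
#' @return A [tibble::tibble] with one row per fibre: `seed`, `insertion`,
#'   `total_length_mm`, `filament_length_mm`, `fibre_length_mm`,
#'   `pennation_deg`, `attachment` (`"direct"`/`"filament"`), `reliable`,
#'   `excluded`, `reason`.
#' @export
classify_and_measure <- function(field, pairs = NULL) {
  stopifnot(inherits(field, "fibre_field"))
  if (is.null(pairs)) pairs <- rank_match(field)
  vs <- field$voxel_size
  thr_px <- field$fibre_diameter_px
  n <- nrow(pairs)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seed <- field$seeds[pairs$seed[i], ]
    ins <- field$apodeme_surface[pairs$insertion[i], ]
    conn <- seed - ins
    lt_px <- vec_norm(conn)
    lt_mm <- lt_px * vs
    if (lt_px < PROJECTION_TOL) {
      out[[i]] <- tibble::tibble(
        seed = pairs$seed[i], insertion = pairs$insertion[i],
        total_length_mm = 0, filament_length_mm = 0, fibre_length_mm = 0,
        pennation_deg = NA_real_, attachment = NA_character_,
        reliable = FALSE, excluded = TRUE, reason = "zero-length connection")
      next
    }
    dir <- conn / lt_px
    if (!is.null(field$muscle_mask)) {
      fil <- grow_filament(ins, dir, field$muscle_mask, vs,
                           threshold_px = thr_px, fallback_px = lt_px)
      fil_px <- fil$length_px
      reliable <- fil$reliable
    } else {
      fil_px <- 0
      reliable <- TRUE
    }
    if (fil_px < thr_px) {       # directly attached
      attachment <- "direct"
      fil_px <- 0
    } else {
      attachment <- "filament"
    }
    fib_mm <- (lt_px - fil_px) * vs
    pen <- vec_angle_deg(dir, field$apodeme_axis)
    pen <- min(pen, 180 - pen)   # pennation is measured against the axis line
    excluded <- fib_mm < 2 * thr_px * vs
    out[[i]] <- tibble::tibble(
      seed = pairs$seed[i], insertion = pairs$insertion[i],
      total_length_mm = lt_mm, filament_length_mm = fil_px * vs,
      fibre_length_mm = fib_mm, pennation_deg = pen,
      attachment = attachment, reliable = reliable,
      excluded = excluded,
      reason = if (excluded) "fibre shorter than twice the fibre diameter" else NA_character_)
  }
  do.call(rbind, out)
}
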