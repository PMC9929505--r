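# Internal helpers: unit conversions, vector algebra, classed conditions.
# Conventions: right-handed coordinates, mm, degrees at interfaces, radians
# internally. Projection lengths onto the rotation plane are |R x v|.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# kPa -> MPa; forces are N = MPa * mm^2 throughout
KPA_PER_MPA <- 1000
GRAVITY_MS2 <- 9.81

# degenerate tolerance for axis projections, mm
PROJECTION_TOL <- 1e-9

bm_stop <- function(msg, class = "bitemech_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "bitemech_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

is_num3 <- function(v) is.numeric(v) && length(v) == 3L && all(is.finite(v))

check_vec3 <- function(v, name) {
  if (!is_num3(v)) bm_stop(sprintf("'%s' must be a finite numeric 3-vector", name))
  as.numeric(v)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v, name = "vector") {
  n <- vec_norm(v)
  if (n < PROJECTION_TOL) {
    bm_stop(sprintf("'%s' has near-zero length; cannot normalize", name),
            class = "bitemech_degenerate_error")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# length of the rejection of v from the unit axis r: |r x v|
projection_length <- function(axis, v) vec_norm(cross3(axis, v))

# angle between two vectors, degrees in [0, 180]
vec_angle_deg <- function(a, b) {
  ca <- sum(a * b) / (vec_norm(a) * vec_norm(b))
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    bm_stop(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) bm_stop(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0) bm_stop(sprintf("'%s' must be >= 0 (got %g)", name, x))
  as.numeric(x)
}
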