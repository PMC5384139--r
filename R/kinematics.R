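#' @name quaternions
#' @title Quaternion utilities (Hamilton convention, scalar first)
#'
#' @description
#' Minimal quaternion algebra used to turn the fused orientation output of
#' two IMUs into a joint angle. Quaternions are length-4 numeric vectors
#' `(w, x, y, z)` (scalar first) or n-by-4 matrices of such rows; the
#' Hamilton product convention is used throughout.
#'
#' @param q,q1,q2,q_ref,q_seg Quaternions: length-4 vectors or n-by-4
#'   matrices (rows are quaternions).
NULL

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4, byrow = TRUE)
  if (ncol(q) != 4) stop("quaternions must have 4 components (w, x, y, z)")
  q
}

#' @describeIn quaternions Rescale to unit norm (error if norm is ~0).
#' @export
quat_normalize <- function(q) {
  qm <- as_quat_matrix(q)
  nrm <- sqrt(rowSums(qm^2))
  if (any(nrm < 1e-8)) stop("cannot normalize a near-zero quaternion")
  out <- qm / nrm
  if (nrow(out) == 1) c(out) else out
}

#' @describeIn quaternions Hamilton product `q1 * q2`.
#' @export
quat_multiply <- function(q1, q2) {
  a <- as_quat_matrix(q1); b <- as_quat_matrix(q2)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  out <- cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
  if (nrow(out) == 1) c(out) else unname(out)
}

#' @describeIn quaternions Conjugate `(w, -x, -y, -z)`.
#' @export
quat_conjugate <- function(q) {
  qm <- as_quat_matrix(q)
  out <- qm %*% diag(c(1, -1, -1, -1))
  if (nrow(out) == 1) c(out) else unname(out)
}

#' @describeIn quaternions Relative rotation taking the reference frame to
#'   the segment frame: `conjugate(q_ref) * q_seg`. Inputs must be unit
#'   quaternions (tolerance 1e-6).
#' @export
quat_relative <- function(q_ref, q_seg) {
  for (q in list(q_ref, q_seg)) {
    nrm <- sqrt(rowSums(as_quat_matrix(q)^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("quat_relative() requires unit quaternions")
  }
  quat_multiply(quat_conjugate(q_ref), q_seg)
}

#' Rotate 3-vectors by quaternions
#'
#' Applies the rotation encoded by unit quaternion(s) `q` to the 3-vector
#' `v` (active rotation, Hamilton convention).
#'
#' @param q Unit quaternion(s), length-4 vector or n-by-4 matrix.
#' @param v Length-3 vector.
#' @return Rotated vector (length 3) or n-by-3 matrix.
#' @export
quat_rotate <- function(q, v) {
  qm <- as_quat_matrix(q)
  w <- qm[, 1]; x <- qm[, 2]; y <- qm[, 3]; z <- qm[, 4]
  # rows of the rotation matrix applied to v
  out <- cbind(
    (1 - 2 * (y^2 + z^2)) * v[1] + 2 * (x * y - w * z) * v[2] + 2 * (x * z + w * y) * v[3],
    2 * (x * y + w * z) * v[1] + (1 - 2 * (x^2 + z^2)) * v[2] + 2 * (y * z - w * x) * v[3],
    2 * (x * z - w * y) * v[1] + 2 * (y * z + w * x) * v[2] + (1 - 2 * (x^2 + y^2)) * v[3]
  )
  if (nrow(out) == 1) c(out) else unname(out)
}

#' Hip angle from sacrum and thigh orientations
#'
#' The angle between the sacrum and thigh longitudinal (y) axes, each
#' rotated into the common world frame by its fused orientation quaternion:
#' `acos` of the clamped dot product, in degrees within [0, 180]. Near 0
#' degrees the thigh is aligned with the sacrum (standing); near 90 degrees
#' the subject is seated. The measure is symmetric in its two arguments and
#' invariant under any rotation applied to both frames, which makes it
#' independent of heading and of the world-frame convention of the
#' orientation filter.
#'
#' @param q_sacrum,q_thigh Unit quaternions (length-4 vectors or n-by-4
#'   matrices of per-sample rows).
#' @return Hip angle(s) in degrees, vectorised over rows.
#' @export
hip_angle <- function(q_sacrum, q_thigh) {
  ys <- as_quat_matrix(q_sacrum)
  yt <- as_quat_matrix(q_thigh)
  a <- quat_rotate(q_sacrum, c(0, 1, 0))
  b <- quat_rotate(q_thigh, c(0, 1, 0))
  a <- if (is.null(dim(a))) matrix(a, ncol = 3) else a
  b <- if (is.null(dim(b))) matrix(b, ncol = 3) else b
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  d <- rowSums(a * b)
  d <- pmin(pmax(d, -1), 1)
  out <- acos(d) * 180 / pi
  if (length(out) == 1) out[[1]] else out
}

#' Upright-posture predicate
#'
#' TRUE when the hip angle is at or below the upright threshold (boundary
#' inclusive). Used to gate gait detection so that shin movement only
#' counts as walking while the subject is standing.
#'
#' @param theta Hip angle(s), degrees, in [0, 180].
#' @param upright_threshold Threshold in degrees (default 30).
#' @return Logical, vectorised over `theta`.
#' @export
is_upright <- function(theta, upright_threshold = 30) {
  stopifnot(all(theta >= 0 & theta <= 180))
  theta <= upright_threshold
}

#' Hip-angle series of a recording
#'
#' Convenience wrapper computing [hip_angle()] at every sample from a
#' recording's sacrum and thigh quaternion series.
#'
#' @param rec A `tug_recording`.
#' @param sacrum_site,thigh_site Site names (defaults `"sacrum"`,
#'   `"r_thigh"`).
#' @return Numeric vector of hip angles in degrees, one per sample.
#' @export
hip_angle_series <- function(rec, sacrum_site = "sacrum", thigh_site = "r_thigh") {
  qs <- rec$sites[[sacrum_site]]$quat
  qt <- rec$sites[[thigh_site]]$quat
  if (is.null(qs) || is.null(qt))
    stop("hip_angle_series(): recording lacks sacrum or thigh quaternions")
  hip_angle(qs, qt)
}
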