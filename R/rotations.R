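#' Rotation-matrix primitives for two-receiver orientation streams
#'
#' Orientation samples from the tracker are ZYX cardan (azimuth-elevation-roll)
#' Euler angles in degrees. Internally sequences of rotations are stored as an
#' N x 9 matrix, each row a 3 x 3 rotation in column-major order, which keeps
#' the per-frame algebra vectorised.
#'
#' @name rotations
#' @keywords internal
NULL

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

#' Build a rotation matrix from ZYX cardan angles
#'
#' Composes `Rz(azimuth) %*% Ry(elevation) %*% Rx(roll)`, the cardan sequence
#' used by electromagnetic trackers reporting azimuth-elevation-roll.
#'
#' @param euler_deg Numeric length-3 vector `c(azimuth, elevation, roll)` in
#'   degrees.
#' @param sequence Rotation sequence; only `"zyx"` is supported.
#' @return A 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @examples
#' euler_to_matrix(c(90, 0, 0)) # maps the x-axis onto the y-axis
#' @export
euler_to_matrix <- function(euler_deg, sequence = "zyx") {
  if (!identical(tolower(sequence), "zyx")) {
    stop("only the ZYX (azimuth-elevation-roll) cardan sequence is supported")
  }
  if (length(euler_deg) != 3L || !all(is.finite(euler_deg))) {
    stop("euler_deg must be three finite angles (degrees)")
  }
  a <- euler_deg * .deg2rad
  ca <- cos(a[1]); sa <- sin(a[1])
  ce <- cos(a[2]); se <- sin(a[2])
  cr <- cos(a[3]); sr <- sin(a[3])
  matrix(c(
    ca * ce, sa * ce, -se,
    ca * se * sr - sa * cr, sa * se * sr + ca * cr, ce * sr,
    ca * se * cr + sa * sr, sa * se * cr - ca * sr, ce * cr
  ), nrow = 3L, ncol = 3L)
}

# Vectorised euler_to_matrix: N x 3 degrees -> N x 9 (column-major rows).
euler_seq_to_rot9 <- function(euler_deg) {
  E <- as.matrix(euler_deg) * .deg2rad
  ca <- cos(E[, 1]); sa <- sin(E[, 1])
  ce <- cos(E[, 2]); se <- sin(E[, 2])
  cr <- cos(E[, 3]); sr <- sin(E[, 3])
  cbind(
    ca * ce, sa * ce, -se,
    ca * se * sr - sa * cr, sa * se * sr + ca * cr, ce * sr,
    ca * se * cr + sa * sr, sa * se * cr - ca * sr, ce * cr
  )
}

#' Recover ZYX cardan angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]. The elevation is confined to
#' (-90, 90) degrees; inputs at the gimbal singularity are rejected.
#'
#' @param R A 3 x 3 rotation matrix.
#' @return Numeric `c(azimuth, elevation, roll)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  se <- -R[3, 1]
  if (abs(se) > 1 - 1e-10) {
    stop("elevation at the +/-90 degree cardan singularity; angles undefined")
  }
  c(
    atan2(R[2, 1], R[1, 1]),
    asin(se),
    atan2(R[3, 2], R[3, 3])
  ) * .rad2deg
}

rot9_to_euler_seq <- function(M9) {
  se <- pmin(1, pmax(-1, -M9[, 3]))
  cbind(
    atan2(M9[, 2], M9[, 1]),
    asin(se),
    atan2(M9[, 6], M9[, 9])
  ) * .rad2deg
}

assert_rotation <- function(R, tol = 1e-6, arg = "matrix") {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) {
    stop(sprintf("%s must be a finite 3 x 3 matrix", arg))
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) <= 0) {
    stop(sprintf("%s is not a rotation (orthonormality/determinant violated)", arg))
  }
  invisible(R)
}

#' Rotation of the head relative to the thorax
#'
#' For head and thorax orientations expressed in a common world frame, the
#' head-on-thorax rotation is `t(thorax) %*% head`.
#'
#' @param head,thorax 3 x 3 rotation matrices.
#' @return The 3 x 3 relative rotation.
#' @export
relative_rotation <- function(head, thorax) {
  assert_rotation(head, arg = "head")
  assert_rotation(thorax, arg = "thorax")
  crossprod(thorax, head)
}

# Per-row C = t(A) %*% B for N x 9 sequences.
rot9_tmult <- function(A9, B9) {
  C9 <- matrix(0, nrow(A9), 9L)
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:3) acc <- acc + A9[, (i - 1L) * 3L + k] * B9[, (j - 1L) * 3L + k]
    C9[, (j - 1L) * 3L + i] <- acc
  }
  C9
}

# Per-row C = A %*% B.
rot9_mult <- function(A9, B9) {
  C9 <- matrix(0, nrow(A9), 9L)
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:3) acc <- acc + A9[, (k - 1L) * 3L + i] * B9[, (j - 1L) * 3L + k]
    C9[, (j - 1L) * 3L + i] <- acc
  }
  C9
}

#' Helical (screw) rotation angle between two orientations
#'
#' The angle of the single-axis rotation carrying `reference` onto `M`,
#' `acos((trace(t(reference) %*% M) - 1) / 2)`, in degrees within \[0, 180\].
#'
#' @param M A 3 x 3 rotation matrix.
#' @param reference Reference orientation (default identity).
#' @return Angle in degrees.
#' @export
helical_angle <- function(M, reference = diag(3)) {
  assert_rotation(M, arg = "M")
  assert_rotation(reference, arg = "reference")
  tr <- sum(diag(crossprod(reference, M)))
  if (tr < -1 - 1e-6 || tr > 3 + 1e-6) stop("trace outside [-1, 3]: not a rotation")
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * .rad2deg
}

# Unit rotation axis from the skew-symmetric part of R; eigen fallback near
# 180 degrees where the skew part vanishes.
rotation_axis <- function(R) {
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nv <- sqrt(sum(v^2))
  if (nv > 1e-12) return(v / nv)
  ev <- eigen(R)
  k <- which.min(abs(ev$values - 1))
  ax <- Re(ev$vectors[, k])
  ax / sqrt(sum(ax^2))
}

# Axis-angle rotation matrix (Rodrigues), axis unit 3-vector, angle degrees.
axis_angle_matrix <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * .deg2rad
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Sequence of head-on-thorax rotations
#'
#' Container pairing a strictly increasing time vector with per-frame 3 x 3
#' rotation matrices. Accepts an N x 3 x 3 array or the internal N x 9 layout.
#'
#' @param time_s Strictly increasing numeric time vector (seconds).
#' @param M An `N x 3 x 3` array of rotation matrices, or an N x 9 matrix of
#'   column-major rotations.
#' @return An object of class `rotation_sequence`.
#' @export
rotation_sequence <- function(time_s, M) {
  if (is.array(M) && length(dim(M)) == 3L) {
    stopifnot(dim(M)[2] == 3L, dim(M)[3] == 3L)
    M9 <- t(apply(M, 1L, as.vector))
  } else {
    M9 <- as.matrix(M)
    stopifnot(ncol(M9) == 9L)
  }
  n <- nrow(M9)
  stopifnot(length(time_s) == n, n >= 2L)
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  err <- max(abs(rot9_tmult(M9, M9) - matrix(rep(as.vector(diag(3)), each = n), n)))
  if (err > 1e-6) stop("rotation_sequence: matrices are not orthonormal")
  structure(list(time_s = as.numeric(time_s), M9 = M9), class = "rotation_sequence")
}

# i-th frame as a 3 x 3 matrix.
rot_seq_matrix <- function(seq, i) matrix(seq$M9[i, ], 3L, 3L)

#' @export
print.rotation_sequence <- function(x, ...) {
  cat(sprintf(
    "<rotation_sequence> %d frames, %.2f s\n",
    nrow(x$M9), diff(range(x$time_s))
  ))
  invisible(x)
}
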