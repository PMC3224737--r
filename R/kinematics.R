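#' From raw orientation streams to helical-axis kinematic signals
#'
#' The processing chain per trial: zero-phase Butterworth low-pass filtering of
#' the raw channels, per-frame rotation matrices from the ZYX cardan angles,
#' head-on-thorax relative rotation, helical angle against the trial-start
#' orientation, 3-D angular speed from the rotation-matrix derivative
#' (`Mdot %*% t(M)`), finite-helical-axis direction over a 4 degree moving
#' window, and cubic-spline resampling of angle and speed to 100 Hz.
#'
#' @name kinematics
NULL

#' Zero-phase Butterworth low-pass filter of a trial recording
#'
#' All 12 orientation/position channels are filtered forward-backward
#' (zero-phase, so peak-speed timing is not shifted); the time channel is
#' untouched. The quoted order is the design order of the underlying filter;
#' the two passes double the effective order.
#'
#' @param rec A [trial_recording()].
#' @param cutoff_hz Cut-off frequency in Hz (must be below Nyquist).
#' @param order Butterworth design order.
#' @return The filtered [trial_recording()].
#' @export
lowpass_filter <- function(rec, cutoff_hz = 20, order = 2) {
  stopifnot(inherits(rec, "trial_recording"))
  fs <- rec$sample_rate_hz
  if (cutoff_hz >= fs / 2) stop("cutoff_hz must be below the Nyquist frequency ", fs / 2)
  if (cutoff_hz <= 0 || order < 1) stop("cutoff_hz and order must be positive")
  n <- nrow(rec$data)
  if (n <= 3L * order) stop("recording too short to filter (need N > 3*order)")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass on signals that do not end at zero
  k <- min(n - 1L, 36L * order)
  out <- rec$data
  for (ch in setdiff(.trial_channels, "t")) {
    x <- rec$data[[ch]]
    xp <- c(2 * x[1L] - x[(k + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - k)])
    yp <- as.numeric(signal::filtfilt(bf, xp))
    out[[ch]] <- yp[(k + 1L):(k + n)]
  }
  rec$data <- out
  rec
}

#' 3-D angular speed of a rotation sequence
#'
#' Attitude angles cannot simply be differentiated; the angular velocity is
#' read off the skew-symmetric part of `Mdot %*% t(M)` (the kinematic relation
#' `Mdot = [omega]x M`), with `Mdot` by central differences (one-sided at the
#' ends). Returns the speed magnitude per frame.
#'
#' @param seq A [rotation_sequence()] with uniform time steps.
#' @return Numeric vector of |omega| in degrees/second.
#' @export
angular_speed <- function(seq) {
  stopifnot(inherits(seq, "rotation_sequence"))
  t <- seq$time_s
  n <- length(t)
  if (n < 3L) stop("need at least 3 frames for angular speed")
  dt <- diff(t)
  if (max(abs(dt - mean(dt))) > 0.01 * mean(dt)) {
    stop("non-uniform sampling (> 1%); resample before computing angular speed")
  }
  h <- mean(dt)
  M9 <- seq$M9
  D9 <- rbind(
    (M9[2L, ] - M9[1L, ]) / h,
    (M9[3:n, ] - M9[1:(n - 2L), ]) / (2 * h),
    (M9[n, ] - M9[n - 1L, ]) / h
  )
  # A = Mdot %*% t(M): A_ij = sum_k D_ik M_jk
  Aij <- function(i, j) {
    acc <- 0
    for (k in 1:3) acc <- acc + D9[, (k - 1L) * 3L + i] * M9[, (k - 1L) * 3L + j]
    acc
  }
  # antisymmetrised components: w = (A32, A13, A21) of (A - t(A)) / 2
  w1 <- (Aij(3L, 2L) - Aij(2L, 3L)) / 2
  w2 <- (Aij(1L, 3L) - Aij(3L, 1L)) / 2
  w3 <- (Aij(2L, 1L) - Aij(1L, 2L)) / 2
  sqrt(w1^2 + w2^2 + w3^2) * .rad2deg
}

#' Finite-helical-axis direction per frame
#'
#' For each frame the axis direction is computed relative to the nearest
#' earlier frame whose helical angular displacement to the current frame is at
#' least `window_deg` (default 4 degrees; smaller rotations give unreliable
#' axes). Frames with no such earlier frame are undefined (`NA` rows).
#' Directions are sign-aligned to the first defined direction so downstream
#' dispersion measures are well defined under the axis sign ambiguity.
#'
#' @param seq A [rotation_sequence()].
#' @param window_deg Angular displacement window in degrees.
#' @return An N x 3 matrix of unit axis directions, `NA` rows where undefined.
#' @export
finite_helical_axis <- function(seq, window_deg = 4) {
  stopifnot(inherits(seq, "rotation_sequence"))
  if (window_deg <= 0) stop("window_deg must be positive")
  M9 <- seq$M9
  n <- nrow(M9)
  # trace(t(M_j) %*% M_i) is the row dot product of the 9-vectors
  G <- tcrossprod(M9)
  cth <- (G - 1) / 2
  cth[cth > 1] <- 1
  cth[cth < -1] <- -1
  ang <- acos(cth) * .rad2deg
  out <- matrix(NA_real_, n, 3L)
  for (i in 2:n) {
    cand <- which(ang[1:(i - 1L), i] >= window_deg)
    if (length(cand) == 0L) next
    j <- max(cand)
    R <- crossprod(matrix(M9[j, ], 3L, 3L), matrix(M9[i, ], 3L, 3L))
    out[i, ] <- rotation_axis(R)
  }
  def <- which(!is.na(out[, 1L]))
  if (length(def) > 1L) {
    ref <- out[def[1L], ]
    flip <- (out[def, , drop = FALSE] %*% ref) < 0
    out[def[flip], ] <- -out[def[flip], , drop = FALSE]
  }
  out
}

#' Compute helical-axis kinematic signals for one trial
#'
#' Runs the full per-trial chain and resamples helical angle and angular speed
#' to the analysis rate (100 Hz) with a natural cubic spline; axis directions
#' are kept at the native rate with their timestamps. The helical angle is
#' referenced to the first-frame head-on-thorax orientation.
#'
#' @param rec A [trial_recording()].
#' @param cutoff_hz,filter_order Passed to [lowpass_filter()].
#' @param window_deg Passed to [finite_helical_axis()].
#' @param target_rate_hz Resampling rate (Hz).
#' @return A `kinematic_signals` object: `grid` (tibble `time_s`,
#'   `helical_angle_deg`, `angular_speed_deg_s` at the analysis rate), `fha`
#'   (tibble of native-rate axis directions), `net_azimuth_deg` (signed axial
#'   rotation actually performed), and trial metadata.
#' @export
compute_signals <- function(rec, cutoff_hz = 20, filter_order = 2,
                            window_deg = 4, target_rate_hz = 100) {
  stopifnot(inherits(rec, "trial_recording"))
  if (max(abs(rec$data$hel), abs(rec$data$tel)) > 80) {
    stop("elevation exceeds 80 degrees: too close to the cardan singularity")
  }
  f <- lowpass_filter(rec, cutoff_hz = cutoff_hz, order = filter_order)
  H9 <- euler_seq_to_rot9(as.matrix(f$data[, c("haz", "hel", "hro")]))
  T9 <- euler_seq_to_rot9(as.matrix(f$data[, c("taz", "tel", "tro")]))
  R9 <- rot9_tmult(T9, H9)          # head relative to thorax, per frame
  t <- f$data$t
  seq <- structure(list(time_s = t, M9 = R9), class = "rotation_sequence")
  # helical angle against the first-frame relative orientation:
  # trace(t(M_1) M_i) is the dot product of 9-vector rows
  tr <- as.numeric(R9 %*% R9[1L, ])
  theta <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * .rad2deg
  speed <- angular_speed(seq)
  fha <- finite_helical_axis(seq, window_deg = window_deg)
  # signed axial (azimuth) excursion, for checking the instructed direction
  eul_rel <- rot9_to_euler_seq(R9)
  az <- eul_rel[, 1L]
  net_az <- az[which.max(abs(az - az[1L]))] - az[1L]
  grid_t <- seq(t[1L], t[length(t)], by = 1 / target_rate_hz)
  th_g <- stats::spline(t, theta, xout = grid_t, method = "natural")$y
  sp_g <- stats::spline(t, speed, xout = grid_t, method = "natural")$y
  structure(
    list(
      grid = tibble::tibble(
        time_s = grid_t,
        helical_angle_deg = th_g,
        angular_speed_deg_s = pmax(sp_g, 0)
      ),
      fha = tibble::tibble(
        time_s = t, fha_x = fha[, 1L], fha_y = fha[, 2L], fha_z = fha[, 3L]
      ),
      net_azimuth_deg = net_az,
      source_sample_rate_hz = rec$sample_rate_hz,
      subject_id = rec$subject_id, trial_index = rec$trial_index,
      direction = rec$direction, session = rec$session
    ),
    class = "kinematic_signals"
  )
}

#' @export
print.kinematic_signals <- function(x, ...) {
  cat(sprintf(
    "<kinematic_signals> subject %s trial %d (%s): %d frames @ 100 Hz, peak speed %.0f deg/s\n",
    x$subject_id, x$trial_index, x$direction, nrow(x$grid),
    max(x$grid$angular_speed_deg_s)
  ))
  invisible(x)
}

#' @method tidy kinematic_signals
#' @export
tidy.kinematic_signals <- function(x, ...) x$grid
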