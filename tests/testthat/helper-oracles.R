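# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# --- quaternion oracle -------------------------------------------------------

quat_mult <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_axis <- function(axis, angle_deg) {
  th <- angle_deg * pi / 360
  c(cos(th), sin(th) * axis / sqrt(sum(axis^2)))
}

# ZYX cardan composition Rz(az) Ry(el) Rx(ro) as a quaternion
quat_from_euler_zyx <- function(euler_deg) {
  quat_mult(
    quat_mult(quat_axis(c(0, 0, 1), euler_deg[1]), quat_axis(c(0, 1, 0), euler_deg[2])),
    quat_axis(c(1, 0, 0), euler_deg[3])
  )
}

quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# rotation angle (deg) between two quaternions, double cover handled
quat_angle <- function(qa, qb) {
  d <- abs(sum(qa * qb / sqrt(sum(qa^2) * sum(qb^2))))
  2 * acos(min(1, d)) * 180 / pi
}

# --- finite-helical-axis exhaustive-search oracle ---------------------------

rot_angle_deg <- function(R) acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi

fha_oracle <- function(time_s, mats, window_deg = 4) {
  n <- length(mats)
  out <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    best <- NA_integer_
    for (j in seq_len(i - 1)) {
      if (rot_angle_deg(crossprod(mats[[j]], mats[[i]])) >= window_deg) best <- j
    }
    if (is.na(best)) next
    R <- crossprod(mats[[best]], mats[[i]])
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    out[i, ] <- v / sqrt(sum(v^2))
  }
  # sign-align to the first defined direction, as the implementation does
  def <- which(!is.na(out[, 1]))
  if (length(def) > 1) {
    ref <- out[def[1], ]
    for (k in def) if (sum(out[k, ] * ref) < 0) out[k, ] <- -out[k, ]
  }
  out
}

# --- minimum-jerk closed forms ----------------------------------------------

# speed shape v(tau) = 30 tau^2 (1 - tau)^2, peak 1.875 at tau = 0.5; the 10%
# threshold crossings are roots of 30 tau^2 (1-tau)^2 = 0.1875 found by
# bisection
minjerk_threshold_roots <- function() {
  f <- function(tau) 30 * tau^2 * (1 - tau)^2 - 0.1875
  c(
    stats::uniroot(f, c(1e-6, 0.5), tol = 1e-12)$root,
    stats::uniroot(f, c(0.5, 1 - 1e-6), tol = 1e-12)$root
  )
}

# --- synthetic signal scaffolding -------------------------------------------

# A kinematic_signals object built directly from an analytic speed profile
# (bypasses the raw-recording pipeline; used to test segmentation in
# isolation).
signals_from_profile <- function(time_s, speed, theta = cumsum(c(0, diff(time_s) *
                                   (utils::head(speed, -1) + utils::tail(speed, -1)) / 2))) {
  structure(
    list(
      grid = tibble::tibble(
        time_s = time_s,
        helical_angle_deg = theta,
        angular_speed_deg_s = speed
      ),
      fha = tibble::tibble(time_s = time_s, fha_x = 0, fha_y = 0, fha_z = 1),
      net_azimuth_deg = max(theta),
      source_sample_rate_hz = 60,
      subject_id = "analytic", trial_index = 1L,
      direction = "left", session = "test1"
    ),
    class = "kinematic_signals"
  )
}

minjerk_speed_grid <- function(peak = 300, rom = 60, pad = 0.5, dt = 0.01) {
  Tm <- 1.875 * rom / peak
  tt <- seq(0, 2 * pad + Tm, by = dt)
  tau <- pmin(pmax((tt - pad) / Tm, 0), 1)
  v <- (rom / Tm) * 30 * tau^2 * (1 - tau)^2
  list(time_s = tt, speed = v, T_move = Tm, t0 = pad)
}

# small valid recording data frame for io tests
make_rec_data <- function(n = 30, fs = 60) {
  t <- (seq_len(n) - 1) / fs
  tibble::tibble(
    t = t, haz = seq(0, 10, length.out = n), hel = 0.5, hro = -0.2,
    hx = 0.01, hy = 0.02, hz = 0.35,
    taz = 0.1, tel = -0.1, tro = 0, tx = 0, ty = 0, tz = 0
  )
}
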