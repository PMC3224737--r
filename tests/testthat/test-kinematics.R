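# helper: rotation_sequence about a fixed axis with angles th (deg)
fixed_axis_seq <- function(th_deg, axis = c(0, 0, 1), fs = 60) {
  mats <- lapply(th_deg, function(a) cervkin:::axis_angle_matrix(axis, a))
  M <- array(0, c(length(th_deg), 3, 3))
  for (i in seq_along(th_deg)) M[i, , ] <- mats[[i]]
  rotation_sequence((seq_along(th_deg) - 1) / fs, M)
}

test_that("lowpass filter has unit DC gain and the analytic Butterworth response", {
  d <- make_rec_data(n = 240)
  d$haz <- 5; d$hel <- -2; d$hro <- 0.3
  rec <- trial_recording(d, "s1")
  out <- lowpass_filter(rec)
  expect_lt(max(abs(out$data$haz - 5)), 1e-9)
  expect_lt(max(abs(out$data$hel + 2)), 1e-9)

  # 5 Hz sinusoid at 60 Hz sampling: zero-phase double pass of a 2nd-order
  # design gives |H|^2 with |H(f)|^2 = 1 / (1 + (f/fc)^4) for the analog
  # prototype; the bilinear design warps slightly, so compare against the
  # digital filter's own squared magnitude
  fs <- 60; f0 <- 5
  d2 <- make_rec_data(n = 600)
  d2$haz <- sin(2 * pi * f0 * d2$t)
  rec2 <- trial_recording(d2, "s1")
  y <- lowpass_filter(rec2)$data$haz
  mid <- 150:450
  amp <- (max(y[mid]) - min(y[mid])) / 2
  bf <- signal::butter(2, 20 / 30)
  zi <- exp(-1i * 2 * pi * f0 / fs * (seq_along(bf$b) - 1))
  H <- sum(bf$b * zi) / sum(bf$a * zi)
  expect_equal(amp, abs(H)^2, tolerance = 1e-3)

  # 25 Hz sinusoid is attenuated
  d3 <- make_rec_data(n = 600)
  d3$haz <- sin(2 * pi * 25 * d3$t)
  amp3 <- diff(range(lowpass_filter(trial_recording(d3, "s1"))$data$haz[mid])) / 2
  expect_lt(amp3, 1)

  expect_error(lowpass_filter(rec, cutoff_hz = 40), "Nyquist")
  expect_error(lowpass_filter(trial_recording(make_rec_data(n = 5), "s1")), "short")
})

test_that("angular_speed recovers constant-rate rotation and is reversal-symmetric", {
  th <- seq(0, 60, by = 100 / 60)   # 100 deg/s at 60 Hz
  s <- fixed_axis_seq(th)
  v <- angular_speed(s)
  expect_lt(max(abs(v[2:(length(v) - 1)] - 100)), 0.1)

  static <- fixed_axis_seq(rep(20, 10))
  expect_lt(max(angular_speed(static)), 1e-9)

  rev_s <- fixed_axis_seq(rev(th))
  expect_equal(angular_speed(rev_s), rev(angular_speed(s)), tolerance = 1e-9)
})

test_that("angular_speed is invariant to a constant world-frame rotation", {
  set.seed(5)
  th <- cumsum(runif(40, 0, 3))
  s <- fixed_axis_seq(th, axis = c(0.2, 0.1, 0.97))
  Q <- euler_to_matrix(c(25, 40, -60))
  M9q <- t(apply(s$M9, 1, function(m) as.vector(Q %*% matrix(m, 3, 3))))
  sq <- rotation_sequence(s$time_s, M9q)
  expect_equal(angular_speed(sq), angular_speed(s), tolerance = 1e-9)
})

test_that("integrated speed matches the net helical angle for single-axis motion", {
  th <- 60 * cervkin:::minjerk_pos(seq(0, 1, length.out = 61))
  s <- fixed_axis_seq(th)
  v <- angular_speed(s)
  total <- sum((utils::head(v, -1) + utils::tail(v, -1)) / 2) / 60
  expect_lt(abs(total - 60), 1)
})

test_that("finite_helical_axis finds fixed axes and honours the 4-degree window", {
  th <- seq(0, 60, length.out = 40)
  s <- fixed_axis_seq(th)
  fha <- finite_helical_axis(s)
  def <- stats::complete.cases(fha)
  expect_gt(sum(def), 30)
  expect_true(all(abs(abs(fha[def, 3]) - 1) < 1e-6))
  expect_true(all(is.na(fha[th < 4, 1])))

  tiny <- fixed_axis_seq(seq(0, 3.5, length.out = 20))
  expect_true(all(is.na(finite_helical_axis(tiny))))
  expect_error(finite_helical_axis(s, window_deg = 0), "positive")
})

test_that("finite_helical_axis matches the exhaustive-search oracle on two-phase motion", {
  # rotate about z, then about x
  th1 <- seq(0, 30, length.out = 25)
  th2 <- seq(0, 25, length.out = 25)
  mats <- c(
    lapply(th1, function(a) cervkin:::axis_angle_matrix(c(0, 0, 1), a)),
    lapply(th2, function(a) {
      cervkin:::axis_angle_matrix(c(0, 0, 1), 30) %*%
        cervkin:::axis_angle_matrix(c(1, 0, 0), a)
    })
  )
  M <- array(0, c(50, 3, 3))
  for (i in 1:50) M[i, , ] <- mats[[i]]
  s <- rotation_sequence((0:49) / 60, M)
  got <- finite_helical_axis(s)
  want <- fha_oracle(s$time_s, mats)
  expect_equal(got, want, tolerance = 1e-9)
  # early directions along z, late directions along x
  expect_lt(max(abs(abs(got[10, 3]) - 1)), 1e-6)
  expect_lt(max(abs(abs(got[50, 1]) - 1)), 1e-6)
})

test_that("finite_helical_axis directions are stable under world-frame relabeling", {
  set.seed(9)
  th <- cumsum(runif(30, 0, 4))
  s <- fixed_axis_seq(th, axis = c(0.3, -0.2, 0.93))
  Q <- euler_to_matrix(c(140, 20, 77))
  M9q <- t(apply(s$M9, 1, function(m) as.vector(Q %*% matrix(m, 3, 3))))
  sq <- rotation_sequence(s$time_s, M9q)
  a <- finite_helical_axis(s); b <- finite_helical_axis(sq)
  def <- stats::complete.cases(a)
  # body-frame axes are unchanged by a constant world-frame relabeling
  expect_equal(abs(a[def, ]), abs(b[def, ]), tolerance = 1e-9)
})

test_that("compute_signals tracks the generator's analytic helical angle", {
  p <- trial_gen_params(peak_speed_deg_s = 150, rom_deg = 60, seed = 7)
  sig <- compute_signals(generate_trial(p))
  Tm <- 1.875 * 60 / 150
  tau <- pmin(pmax((sig$grid$time_s - 0.5) / Tm, 0), 1)
  theta_true <- 60 * cervkin:::minjerk_pos(tau)
  expect_lt(max(abs(sig$grid$helical_angle_deg - theta_true)), 0.5)
  # resampling contract
  dur <- diff(range(generate_trial(p)$data$t))
  expect_equal(nrow(sig$grid), round(dur * 100) + 1)
})

test_that("a static recording yields near-zero speed", {
  d <- make_rec_data(n = 120)
  d$haz <- 25; d$hel <- 3; d$hro <- -1
  sig <- compute_signals(trial_recording(d, "s1"))
  expect_lt(max(sig$grid$angular_speed_deg_s), 1e-6)
})

test_that("recordings near the cardan singularity are rejected", {
  d <- make_rec_data(n = 120)
  d$hel <- 85
  expect_error(compute_signals(trial_recording(d, "s1")), "elevation")
})
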