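#' Synthetic fast-axial-rotation trials and cohorts
#'
#' The generator emulates the test protocol: a seated subject rotates the
#' head as fast as possible to one side. The primary rotation angle follows a
#' time-warped minimum-jerk trajectory (the warp exponent shifts the time of
#' peak speed, setting the acceleration/deceleration asymmetry), with an
#' optional band-limited sinusoidal speed ripple (jerkiness), a rotation axis
#' that precesses inside a cone via a slow random walk (conjunct-axis wobble),
#' additive Gaussian sensor noise on the cardan angles, and 0.5 s of
#' stationary padding on both sides so segmentation sees sub-threshold speed.
#' Cohort generation draws per-subject latent parameters from group
#' distributions calibrated to the neck-pain (NS) and control (CON) cohort
#' statistics, with a between-session component for test-retest designs and a
#' correlated questionnaire block for association modelling.
#'
#' @name synthetic-data
NULL

#' Parameters of one synthetic trial
#'
#' @param peak_speed_deg_s Target peak rotational speed (deg/s).
#' @param rom_deg Target amplitude of the rotation (deg). The minimum-jerk
#'   base duration follows as `T = 1.875 * rom / peak`.
#' @param ad_asym Target acceleration/deceleration ratio (> 0; 1 = symmetric).
#' @param ripple_frac Speed-ripple amplitude as a fraction of peak speed.
#' @param axis_wobble_deg Cone half-angle (deg) of the axis random walk.
#' @param sensor_noise_deg SD of additive Gaussian angle noise (deg).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param direction `"left"` (positive azimuth) or `"right"`.
#' @param pad_s Stationary padding before and after the movement (s).
#' @param seed Integer seed; same seed, same recording.
#' @return A `trial_gen_params` list.
#' @export
trial_gen_params <- function(peak_speed_deg_s = 300, rom_deg = 60, ad_asym = 1,
                             ripple_frac = 0, axis_wobble_deg = 0,
                             sensor_noise_deg = 0, sample_rate_hz = 60,
                             direction = c("left", "right"), pad_s = 0.5,
                             seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(peak_speed_deg_s > 0, rom_deg > 0, ad_asym > 0, ripple_frac >= 0,
            axis_wobble_deg >= 0, sensor_noise_deg >= 0, sample_rate_hz > 0)
  structure(
    list(
      peak_speed_deg_s = peak_speed_deg_s, rom_deg = rom_deg, ad_asym = ad_asym,
      ripple_frac = ripple_frac, axis_wobble_deg = axis_wobble_deg,
      sensor_noise_deg = sensor_noise_deg, sample_rate_hz = sample_rate_hz,
      direction = direction, pad_s = pad_s, seed = as.integer(seed)
    ),
    class = "trial_gen_params"
  )
}

# Minimum-jerk position x(tau) in [0,1] and speed shape x'(tau).
minjerk_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
minjerk_vel <- function(tau) 30 * tau^2 * (1 - tau)^2

# Warp exponent alpha such that the peak of d/dtau minjerk_pos(tau^alpha)
# falls at tau = r / (1 + r), giving A/D-ratio approximately r.
warp_exponent <- function(ad_asym) {
  if (abs(ad_asym - 1) < 1e-9) return(1)
  target <- ad_asym / (1 + ad_asym)
  tau <- seq(0.001, 0.999, length.out = 2001L)
  obj <- function(alpha) {
    v <- minjerk_vel(tau^alpha) * alpha * tau^(alpha - 1)
    (tau[which.max(v)] - target)^2
  }
  stats::optimize(obj, c(0.25, 4))$minimum
}

#' Generate one synthetic trial recording
#'
#' @param p A [trial_gen_params()].
#' @return A [trial_recording()] sampled at `p$sample_rate_hz`.
#' @export
generate_trial <- function(p) {
  stopifnot(inherits(p, "trial_gen_params"))
  set.seed(p$seed)
  fs <- p$sample_rate_hz
  A <- p$rom_deg
  alpha <- warp_exponent(p$ad_asym)
  # peak factor of the (possibly warped) unit speed shape; 1.875 when
  # symmetric. Duration is set so the realized peak equals the configured one.
  tg <- seq(1e-4, 1 - 1e-4, length.out = 4001L)
  vshape_max <- max(minjerk_vel(tg^alpha) * alpha * tg^(alpha - 1))
  Tm <- vshape_max * A / p$peak_speed_deg_s
  total <- 2 * p$pad_s + Tm
  n <- round(total * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  tau <- pmin(pmax((t - p$pad_s) / Tm, 0), 1)
  theta <- A * minjerk_pos(tau^alpha)
  if (p$ripple_frac > 0) {
    f_rip <- stats::runif(1L, 3, 10)
    phase <- stats::runif(1L, 0, 2 * pi)
    env <- 16 * tau^2 * (1 - tau)^2
    amp <- p$ripple_frac * p$peak_speed_deg_s / (2 * pi * f_rip)
    theta <- theta + amp * sin(2 * pi * f_rip * (t - p$pad_s) + phase) * env
  }
  wobble <- p$axis_wobble_deg
  for (attempt in 1:5) {
    if (wobble > 0) {
      # axis precesses only while the head moves; outside the movement the
      # axis is frozen so the padded ends stay stationary
      mv <- which(tau > 0 & tau < 1)
      nm <- length(mv)
      beta <- numeric(nm); phi <- numeric(nm)
      beta[1L] <- stats::runif(1L, 0, wobble) * .deg2rad
      phi[1L] <- stats::runif(1L, 0, 2 * pi)
      step_b <- wobble * .deg2rad / 5
      wb <- wobble * .deg2rad
      for (i in seq_len(nm)[-1L]) {
        b <- beta[i - 1L] + stats::rnorm(1L, 0, step_b)
        # reflect into [0, wobble]
        b <- abs(b); if (b > wb) b <- 2 * wb - b
        beta[i] <- min(max(b, 0), wb)
        phi[i] <- phi[i - 1L] + stats::rnorm(1L, 0, 0.3)
      }
      k <- min(9L, nm)
      sm <- function(x) {
        y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2L))
        y[is.na(y)] <- x[is.na(y)]
        y
      }
      bs_m <- sm(beta); ps_m <- sm(phi)
      bs <- c(rep(bs_m[1L], min(mv) - 1L), bs_m, rep(bs_m[nm], n - max(mv)))
      ps <- c(rep(ps_m[1L], min(mv) - 1L), ps_m, rep(ps_m[nm], n - max(mv)))
      ax <- cbind(sin(bs) * cos(ps), sin(bs) * sin(ps), cos(bs))
    } else {
      ax <- matrix(rep(c(0, 0, 1), each = n), n)
    }
    sgn <- if (p$direction == "left") 1 else -1
    th_r <- sgn * theta * .deg2rad
    ct <- cos(th_r); st <- sin(th_r); vt <- 1 - ct
    x <- ax[, 1L]; y <- ax[, 2L]; z <- ax[, 3L]
    # Rodrigues per frame, column-major N x 9
    M9 <- cbind(
      ct + x * x * vt, x * y * vt + z * st, x * z * vt - y * st,
      x * y * vt - z * st, ct + y * y * vt, y * z * vt + x * st,
      x * z * vt + y * st, y * z * vt - x * st, ct + z * z * vt
    )
    eul <- rot9_to_euler_seq(M9)
    if (max(abs(eul[, 2L])) <= 80) break
    warning("generated elevation exceeded 80 degrees; retrying with reduced wobble")
    wobble <- wobble / 2
  }
  noise <- function() stats::rnorm(n, 0, p$sensor_noise_deg)
  dat <- tibble::tibble(
    t = t,
    haz = eul[, 1L] + noise(), hel = eul[, 2L] + noise(), hro = eul[, 3L] + noise(),
    hx = 0.02 + stats::rnorm(n, 0, 1e-4), hy = stats::rnorm(n, 0, 1e-4),
    hz = 0.35 + stats::rnorm(n, 0, 1e-4),
    taz = noise(), tel = noise(), tro = noise(),
    tx = stats::rnorm(n, 0, 1e-4), ty = stats::rnorm(n, 0, 1e-4),
    tz = stats::rnorm(n, 0, 1e-4)
  )
  trial_recording(dat, subject_id = "synthetic", direction = p$direction,
                  sample_rate_hz = fs)
}

#' Group-level generator configuration
#'
#' Defaults are the pooled cohort statistics of the fast-rotation test:
#' Peak Speed 348 +/- 92 (CON) vs 226 +/- 88 (NS) deg/s, ROM 61.5 +/- 8.3 vs
#' 52.7 +/- 9.2 deg, A/D-ratio 0.81 +/- 0.24 vs 0.74 +/- 0.22, with speed
#' ripple scaled to the observed deviation from the minimum-jerk shape
#' (SID 13.7 vs 18.1%) and axis wobble calibrated to the conjunct-movement
#' condition numbers (CM 14.5 vs 17.6 a.u.). Ages follow the cohort
#' descriptives, negatively correlated with ROM and Peak Speed.
#'
#' @param n_ns,n_con Group sizes.
#' @param sessions 1 or 2 (test-retest).
#' @param between_session_frac Fraction of the between-subject variance
#'   re-drawn per session (sets test-retest noise).
#' @param trial_jitter_frac SD of multiplicative trial-to-trial jitter.
#' @param groups Named list of per-group parameter distributions; see default.
#' @param lbp_prob Probability of concurrent low-back pain among NS subjects.
#' @param seed Integer seed.
#' @return A `cohort_gen_config` list.
#' @export
cohort_gen_config <- function(n_ns = 118, n_con = 49, sessions = 1,
                              between_session_frac = 0.2, trial_jitter_frac = 0.05,
                              groups = NULL, lbp_prob = 62 / 118, seed = 1L) {
  stopifnot(n_ns >= 1L, n_con >= 1L, sessions %in% c(1L, 2L),
            between_session_frac >= 0, trial_jitter_frac >= 0)
  if (is.null(groups)) {
    groups <- list(
      CON = list(
        peak = c(348, 92), rom = c(61.5, 8.3), ad = c(0.81, 0.24),
        ripple = c(0.06, 0.03), wobble = c(12, 3),
        noise = 0.05, age = c(46.5, 10)
      ),
      NS = list(
        peak = c(226, 88), rom = c(52.7, 9.2), ad = c(0.74, 0.22),
        ripple = c(0.09, 0.04), wobble = c(5.5, 2),
        noise = 0.05, age = c(50.5, 9)
      )
    )
  }
  structure(
    list(n_ns = n_ns, n_con = n_con, sessions = as.integer(sessions),
         between_session_frac = between_session_frac,
         trial_jitter_frac = trial_jitter_frac, groups = groups,
         lbp_prob = lbp_prob, seed = as.integer(seed)),
    class = "cohort_gen_config"
  )
}

# One subject's latent parameters, truncated at physiologic bounds.
draw_subject_latents <- function(gp) {
  z_age <- stats::rnorm(1L)
  age <- gp$age[1L] + gp$age[2L] * z_age
  # ROM and Peak Speed decline with age (copula correlations ~ -0.5 / -0.3)
  z_rom <- -0.5 * z_age + sqrt(1 - 0.25) * stats::rnorm(1L)
  z_peak <- -0.3 * z_age + sqrt(1 - 0.09) * stats::rnorm(1L)
  list(
    age = min(max(age, 20), 70),
    peak = min(max(gp$peak[1L] + gp$peak[2L] * z_peak, 60), 650),
    rom = min(max(gp$rom[1L] + gp$rom[2L] * z_rom, 25), 85),
    ad = rtruncnorm(1L, gp$ad[1L], gp$ad[2L], 0.3, 2.5),
    ripple = rtruncnorm(1L, gp$ripple[1L], gp$ripple[2L], 0.02, 0.45),
    wobble = rtruncnorm(1L, gp$wobble[1L], gp$wobble[2L], 1, 20),
    noise = gp$noise
  )
}

#' Generate a synthetic cohort
#'
#' Per subject, latent kinematic parameters are drawn from the configured
#' group distributions; each session re-draws a between-session component and
#' contributes six trials in alternating directions with trial-to-trial
#' jitter. The subject table records group, age, low-back-pain status and the
#' latent peak speed (generator ground truth, used by
#' [generate_questionnaire_block()]).
#'
#' @param cfg A [cohort_gen_config()].
#' @return A `cohort_dataset`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_gen_config"))
  set.seed(cfg$seed)
  subjects <- tibble::tibble(
    subject_id = c(sprintf("NS%03d", seq_len(cfg$n_ns)),
                   sprintf("CON%03d", seq_len(cfg$n_con))),
    group = rep(c("NS", "CON"), c(cfg$n_ns, cfg$n_con))
  )
  nsub <- nrow(subjects)
  lat <- vector("list", nsub)
  for (i in seq_len(nsub)) {
    lat[[i]] <- draw_subject_latents(cfg$groups[[subjects$group[i]]])
  }
  subjects$age_years <- vapply(lat, `[[`, numeric(1L), "age")
  subjects$low_back_pain <- ifelse(
    subjects$group == "NS", stats::runif(nsub) < cfg$lbp_prob, NA
  )
  subjects$latent_peak_speed <- vapply(lat, `[[`, numeric(1L), "peak")
  recordings <- list()
  ri <- 0L
  for (i in seq_len(nsub)) {
    L <- lat[[i]]
    gp <- cfg$groups[[subjects$group[i]]]
    start_right <- i %% 2L == 0L
    for (s in seq_len(cfg$sessions)) {
      peak_s <- max(60, L$peak + stats::rnorm(1L, 0, sqrt(cfg$between_session_frac) * gp$peak[2L]))
      rom_s <- min(max(L$rom + stats::rnorm(1L, 0, sqrt(cfg$between_session_frac) * gp$rom[2L]), 25), 85)
      ad_s <- rtruncnorm(1L, L$ad, sqrt(cfg$between_session_frac) * gp$ad[2L], 0.3, 2.5)
      for (k in 1:6) {
        dir <- if (xor(start_right, k %% 2L == 1L)) "left" else "right"
        jit <- function(x) x * (1 + stats::rnorm(1L, 0, cfg$trial_jitter_frac))
        p <- trial_gen_params(
          peak_speed_deg_s = max(50, jit(peak_s)),
          rom_deg = min(max(jit(rom_s), 20), 90),
          ad_asym = min(max(jit(ad_s), 0.3), 2.5),
          ripple_frac = max(0.01, jit(L$ripple)),
          axis_wobble_deg = min(max(jit(L$wobble), 0.5), 25),
          sensor_noise_deg = L$noise,
          direction = dir,
          seed = sample.int(.Machine$integer.max - 1L, 1L)
        )
        rec <- generate_trial(p)
        rec$subject_id <- subjects$subject_id[i]
        rec$trial_index <- k
        rec$session <- paste0("test", s)
        ri <- ri + 1L
        recordings[[ri]] <- rec
      }
    }
  }
  cohort_dataset(subjects, recordings)
}

# 44-predictor questionnaire schema: instrument totals are continuous, the
# symptom/function items use the six-level scale.
questionnaire_schema <- function() {
  cont <- c("tsk", "sf36_pf", "sf36_bp", "sf36_gh", "sf36_vt", "sf36_sf",
            "sf36_mh", "dash_1_19", "age", "symptom_duration", "physical_activity")
  lev6 <- c("ndi_pain_intensity", "ndi_headache", "ndi_concentration",
            "ndi_sleeping", "ndi_car_driving",
            "dash_arm_shoulder_hand_pain", "dash_tingling", "dash_weakness",
            "bend_forward", "bend_backward", "bend_right", "bend_left",
            "turn_right", "turn_left", "run", "jaw_disorder",
            "difficulty_swallowing", "clumsiness", "dizziness",
            "balance_disturbance", "sensory_disturbance", "light_sensitivity",
            "sound_sensitivity", "nausea", "pain_activity", "pain_rest",
            "neck_stiffness", "neck_tenderness", "neck_tension", "neck_fatigue",
            "neck_weakness", "neck_crepitations", "neck_lockings")
  list(continuous = cont, six_level = lev6, all = c(cont, lev6))
}

# Default ordering in which predictors become informative (strongest known
# associates of reduced peak speed first).
.informative_order <- c(
  "ndi_car_driving", "run", "ndi_sleeping", "sf36_bp",
  "dash_arm_shoulder_hand_pain", "bend_left", "bend_right",
  "ndi_pain_intensity", "bend_backward", "turn_right", "turn_left"
)

#' Generate the 44-predictor questionnaire block
#'
#' Adds the questionnaire predictors to a cohort's subject table. The first
#' `n_informative` predictors (difficulty/symptom items known to associate
#' with reduced peak speed) are generated from a Gaussian copula with the
#' subject's latent peak speed at correlation `effect_r`; six-level items are
#' quantile-discretised to the 1..6 scale, instrument totals stay continuous.
#' The remaining predictors are independent noise. About 2% of cells (except
#' age) are set missing at random.
#'
#' @param cohort A `cohort_dataset` whose subject table has
#'   `latent_peak_speed` (i.e. produced by [generate_cohort()]).
#' @param n_informative Number of informative predictors (0..44).
#' @param effect_r Copula correlation with latent peak speed (|r| < 1);
#'   difficulty items typically have negative r.
#' @param seed Integer seed.
#' @param missing_prob Per-cell missingness probability.
#' @return The subject tibble with 44 predictor columns appended.
#' @export
generate_questionnaire_block <- function(cohort, n_informative = 11,
                                         effect_r = -0.35, seed = 1L,
                                         missing_prob = 0.02) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (abs(effect_r) >= 1) stop("|effect_r| must be below 1")
  subj <- cohort$subjects
  if (!"latent_peak_speed" %in% names(subj)) {
    stop("subject table lacks latent_peak_speed (generate the cohort first)")
  }
  sch <- questionnaire_schema()
  stopifnot(n_informative <= length(sch$all))
  set.seed(seed)
  n <- nrow(subj)
  zp <- as.numeric(scale(subj$latent_peak_speed))
  informative <- c(.informative_order,
                   setdiff(sch$all, c(.informative_order, "age")))[seq_len(n_informative)]
  draw <- function(name) {
    z <- if (name %in% informative) {
      # enforce the realized (sample) correlation with the latent: draw noise,
      # residualize it against the latent and mix at exactly effect_r
      e <- stats::rnorm(n)
      e <- stats::resid(stats::lm(e ~ zp))
      e <- as.numeric(scale(e))
      effect_r * zp + sqrt(1 - effect_r^2) * e
    } else {
      stats::rnorm(n)
    }
    if (name %in% sch$six_level) {
      as.numeric(cut(stats::pnorm(z), breaks = seq(0, 1, by = 1 / 6),
                     labels = FALSE, include.lowest = TRUE))
    } else {
      switch(name,
        age = subj$age_years,
        tsk = pmin(pmax(30 + 10 * z, 17), 68),
        symptom_duration = exp(4.5 + 0.8 * z),
        physical_activity = pmin(pmax(4 + z, 1), 6),
        dash_1_19 = pmin(pmax(25 + 12 * z, 0), 100),
        pmin(pmax(50 + 20 * z, 0), 100)   # SF-36 style 0-100 scales
      )
    }
  }
  block <- purrr::map_dfc(stats::setNames(sch$all, sch$all), draw)
  for (cn in setdiff(sch$all, "age")) {
    miss <- stats::runif(n) < missing_prob
    block[[cn]][miss] <- NA_real_
  }
  dplyr::bind_cols(subj, block)
}

#' Map axis wobble to expected conjunct-movement condition numbers
#'
#' The condition number of a noisy axis cloud has no simple closed form; this
#' utility estimates the CM the pipeline recovers for given wobble settings by
#' simulation, for calibrating [cohort_gen_config()].
#'
#' @param wobble_deg Vector of cone half-angles to probe.
#' @param n_trials Trials per setting.
#' @param seed Integer seed.
#' @param ... Other [trial_gen_params()] settings held fixed.
#' @return Tibble with `wobble_deg`, mean and SD of recovered CM.
#' @export
calibrate_wobble_to_cm <- function(wobble_deg, n_trials = 10, seed = 1L, ...) {
  purrr::map_dfr(wobble_deg, function(w) {
    cms <- vapply(seq_len(n_trials), function(i) {
      p <- trial_gen_params(axis_wobble_deg = w, sensor_noise_deg = 0.2,
                            ripple_frac = 0.1, seed = seed + 7919L * i, ...)
      m <- process_trial(generate_trial(p))
      m$cm
    }, numeric(1L))
    tibble::tibble(wobble_deg = w, cm_mean = mean(cms, na.rm = TRUE),
                   cm_sd = stats::sd(cms, na.rm = TRUE))
  })
}
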