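#' Six kinematic variables per trial and per subject
#'
#' Per outward rotation the pipeline reports: Peak Speed (deg/s), ROM (deg,
#' helical-angle difference between movement start and stop), Move Time and
#' time-to-peak (s, on the extrapolated profile), NPA (peak/mean speed;
#' 1.875 for an ideal minimum-jerk movement), A/D-ratio (acceleration time
#' over deceleration time), SID (% RMSE from a displacement-matched
#' minimum-jerk speed profile), and CM (condition number of the
#' finite-helical-axis directions during the movement; small values mean
#' large conjunct motion).
#'
#' @name trial-metrics
NULL

#' Speed index of deviation from a minimum-jerk profile
#'
#' Fits the minimum-jerk speed profile
#' `v(tau) = (A/T) * 30 tau^2 (1 - tau)^2` with duration `T` equal to the
#' extrapolated Move Time and amplitude `A` equal to the time-integral of the
#' extrapolated speed (displacement-matched, parameter-free), then reports
#' `100 * RMSE / mean(v_obs)` (or peak-normalised).
#'
#' @param seg An extrapolated `movement_segment`.
#' @param denominator Normalisation of the RMSE: mean or peak observed speed.
#' @return SID in percent.
#' @export
compute_sid <- function(seg, denominator = c("mean", "peak")) {
  denominator <- match.arg(denominator)
  tt <- seg$extrapolated_time_s
  v <- seg$extrapolated_speed_deg_s
  if (is.null(tt)) stop("segment must be extrapolated first")
  Tm <- tt[length(tt)] - tt[1L]
  A <- trapz(tt, v)
  if (A <= 0) stop("zero displacement: SID undefined")
  tau <- (tt - tt[1L]) / Tm
  v_fit <- (A / Tm) * 30 * tau^2 * (1 - tau)^2
  rmse <- sqrt(mean((v_fit - v)^2))
  den <- if (denominator == "mean") A / Tm else max(v)
  100 * rmse / den
}

#' Conjunct movement: condition number of axis directions
#'
#' Stacks the sign-aligned finite-helical-axis unit vectors observed during
#' the movement into a K x 3 matrix and returns the ratio of its largest to
#' smallest singular value. A small value indicates large changes in axis
#' direction (more conjunct movement). Degenerate (collinear) clouds are
#' capped.
#'
#' @param fha_dirs K x 3 matrix of unit axis directions (rows may repeat).
#' @param cap Value returned when the smallest singular value vanishes.
#' @return Condition number (>= 1).
#' @export
compute_cm <- function(fha_dirs, cap = 1e6) {
  X <- as.matrix(fha_dirs)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stop("insufficient rotation: need at least 3 defined axis directions")
  ref <- X[1L, ]
  flip <- (X %*% ref) < 0
  X[flip, ] <- -X[flip, , drop = FALSE]
  sv <- svd(X, nu = 0L, nv = 0L)$d
  if (sv[3L] < 1e-12) return(cap)
  sv[1L] / sv[3L]
}

#' Compute the kinematic variables for one segmented trial
#'
#' @param signals A `kinematic_signals` object.
#' @param seg The extrapolated `movement_segment` for the same trial.
#' @param sid_denominator Passed to [compute_sid()].
#' @return A one-row tibble (`trial metrics`): `peak_speed_deg_s`, `rom_deg`,
#'   `move_time_s`, `ttp_s`, `npa`, `ad_ratio`, `sid_pct`, `cm`, `valid`,
#'   `invalid_reason`.
#' @export
compute_metrics <- function(signals, seg, sid_denominator = "mean") {
  stopifnot(inherits(signals, "kinematic_signals"), inherits(seg, "movement_segment"))
  if (is.null(seg$extrapolated_time_s)) stop("segment must be extrapolated first")
  g <- signals$grid
  ext_t <- seg$extrapolated_time_s
  ext_v <- seg$extrapolated_speed_deg_s
  move_time <- ext_t[length(ext_t)] - ext_t[1L]
  t_peak <- g$time_s[seg$peak_idx]
  ttp <- t_peak - ext_t[1L]
  if (move_time <= ttp || ttp <= 0) stop("inconsistent segmentation: TTP outside Move Time")
  rom <- g$helical_angle_deg[seg$stop_idx] - g$helical_angle_deg[seg$start_idx]
  mean_speed <- trapz(ext_t, ext_v) / move_time
  cm <- tryCatch({
    in_seg <- signals$fha$time_s >= g$time_s[seg$start_idx] &
      signals$fha$time_s <= g$time_s[seg$stop_idx]
    compute_cm(as.matrix(signals$fha[in_seg, c("fha_x", "fha_y", "fha_z")]))
  }, error = function(e) NA_real_)
  tibble::tibble(
    subject_id = signals$subject_id,
    session = signals$session,
    trial_index = signals$trial_index,
    direction = signals$direction,
    peak_speed_deg_s = seg$peak_speed_deg_s,
    rom_deg = rom,
    move_time_s = move_time,
    ttp_s = ttp,
    npa = seg$peak_speed_deg_s / mean_speed,
    ad_ratio = ttp / (move_time - ttp),
    sid_pct = compute_sid(seg, denominator = sid_denominator),
    cm = cm,
    valid = TRUE,
    invalid_reason = NA_character_
  )
}

#' Flag atypical trials
#'
#' Automated screen replacing manual curation of atypical movements. A trial
#' is invalidated when any of these hold: peak speed below `min_peak_speed`;
#' ROM below `min_rom`; net axial rotation opposite the instructed direction;
#' or a multi-peaked speed profile (two local maxima within 20% of the
#' maximum separated by a drop below 50% of the maximum).
#'
#' @param metrics One-row trial metrics tibble from [compute_metrics()].
#' @param signals The trial's `kinematic_signals`.
#' @param min_peak_speed,min_rom Validity thresholds (deg/s, deg).
#' @return The metrics row with `valid` / `invalid_reason` updated.
#' @export
flag_atypical <- function(metrics, signals, min_peak_speed = 30, min_rom = 10) {
  reason <- NULL
  if (metrics$peak_speed_deg_s < min_peak_speed) {
    reason <- "slow"
  } else if (metrics$rom_deg < min_rom) {
    reason <- "small-rom"
  } else {
    # instructed left = positive azimuth excursion of head on thorax
    want <- if (identical(signals$direction, "left")) 1 else -1
    if (sign(signals$net_azimuth_deg) != want) reason <- "direction"
  }
  if (is.null(reason)) {
    v <- signals$grid$angular_speed_deg_s
    peak <- max(v)
    loc <- which(diff(sign(diff(v))) == -2L) + 1L
    big <- loc[v[loc] >= 0.8 * peak]
    if (length(big) >= 2L) {
      for (a in 1:(length(big) - 1L)) {
        if (min(v[big[a]:big[a + 1L]]) < 0.5 * peak) {
          reason <- "multi-peak"
          break
        }
      }
    }
  }
  if (!is.null(reason)) {
    metrics$valid <- FALSE
    metrics$invalid_reason <- reason
  }
  metrics
}

#' Average trial metrics within a subject and session
#'
#' Arithmetic mean of each kinematic variable over valid trials, left and
#' right rotations pooled.
#'
#' @param trials Tibble of trial metrics rows (one subject and session).
#' @return One-row tibble of per-variable means plus `n_valid_trials`, or a
#'   zero-row tibble if no trial is valid.
#' @export
aggregate_subject <- function(trials) {
  ok <- dplyr::filter(trials, .data$valid)
  if (nrow(ok) == 0L) {
    return(tibble::tibble(
      subject_id = character(0), session = character(0), n_valid_trials = integer(0),
      peak_speed_deg_s = numeric(0), rom_deg = numeric(0), move_time_s = numeric(0),
      ttp_s = numeric(0), npa = numeric(0), ad_ratio = numeric(0),
      sid_pct = numeric(0), cm = numeric(0)
    ))
  }
  ok |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(
      n_valid_trials = dplyr::n(),
      dplyr::across(
        c("peak_speed_deg_s", "rom_deg", "move_time_s", "ttp_s",
          "npa", "ad_ratio", "sid_pct", "cm"),
        ~ mean(.x, na.rm = TRUE)
      ),
      .groups = "drop"
    )
}

#' Process one recording end to end
#'
#' @param rec A [trial_recording()].
#' @param sid_denominator Passed to [compute_sid()].
#' @param ... Passed to [compute_signals()].
#' @return One-row trial metrics tibble; pipeline failures (truncated or
#'   unterminated movements) yield an invalid row with the failure reason.
#' @export
process_trial <- function(rec, sid_denominator = "mean", ...) {
  tryCatch({
    sig <- compute_signals(rec, ...)
    seg <- detect_segment(sig)
    seg <- extrapolate_speed(seg, sig)
    m <- compute_metrics(sig, seg, sid_denominator = sid_denominator)
    flag_atypical(m, sig)
  }, error = function(e) {
    tibble::tibble(
      subject_id = rec$subject_id, session = rec$session,
      trial_index = rec$trial_index, direction = rec$direction,
      peak_speed_deg_s = NA_real_, rom_deg = NA_real_, move_time_s = NA_real_,
      ttp_s = NA_real_, npa = NA_real_, ad_ratio = NA_real_, sid_pct = NA_real_,
      cm = NA_real_, valid = FALSE, invalid_reason = conditionMessage(e)
    )
  })
}

#' Process a cohort: per-trial metrics and subject-level means
#'
#' Runs every non-practice recording through the pipeline, flags atypical
#' trials, and averages the kinematic variables over valid trials per subject
#' and session (left/right pooled). Subject metadata (group, age, other
#' columns) is joined onto the subject-level table.
#'
#' @param cohort A `cohort_dataset`.
#' @param sid_denominator Passed to [compute_sid()].
#' @param ... Passed to [compute_signals()].
#' @return List with `trials` (per-trial metrics tibble) and `subjects`
#'   (subject x session means joined with subject metadata).
#' @export
process_cohort <- function(cohort, sid_denominator = "mean", ...) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  recs <- Filter(function(r) !r$practice, cohort$recordings)
  trials <- purrr::map_dfr(recs, process_trial, sid_denominator = sid_denominator, ...)
  subj <- aggregate_subject(trials) |>
    dplyr::left_join(cohort$subjects, by = "subject_id")
  list(trials = trials, subjects = subj)
}
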