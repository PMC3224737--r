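#' Movement segmentation and quintic extrapolation of the speed profile
#'
#' The outward rotation is delimited on the 100 Hz grid by a threshold of 10%
#' of peak speed. Because the profile therefore starts and stops at non-zero
#' speed, each side is extended to zero speed by a quintic polynomial that
#' continues the observed profile smoothly.
#'
#' @name segmentation
NULL

#' Detect the outward movement segment
#'
#' Peak speed is the maximum of the angular-speed signal on the analysis grid.
#' Start is the last sample at or below 10% of peak before the peak, stop the
#' first at or below the threshold after it.
#'
#' @param signals A `kinematic_signals` object from [compute_signals()].
#' @param threshold_frac Threshold as a fraction of peak speed.
#' @return A `movement_segment`: indices into the grid, peak speed and
#'   threshold.
#' @export
detect_segment <- function(signals, threshold_frac = 0.1) {
  stopifnot(inherits(signals, "kinematic_signals"))
  v <- signals$grid$angular_speed_deg_s
  n <- length(v)
  ip <- which.max(v)
  if (ip == 1L || ip == n) stop("truncated trial: peak speed at the series boundary")
  peak <- v[ip]
  thr <- threshold_frac * peak
  pre <- which(v[1:(ip - 1L)] <= thr)
  if (length(pre) == 0L) stop("truncated trial: speed never at/below threshold before the peak")
  post <- which(v[(ip + 1L):n] <= thr)
  if (length(post) == 0L) stop("unterminated movement: speed never drops to threshold after the peak")
  structure(
    list(
      start_idx = max(pre), stop_idx = ip + min(post), peak_idx = ip,
      peak_speed_deg_s = peak, threshold_deg_s = thr,
      extrapolated_time_s = NULL, extrapolated_speed_deg_s = NULL
    ),
    class = "movement_segment"
  )
}

# Quintic side extension on [0, delta]: endpoint (u = 0) has v = v' = v'' = 0,
# boundary (u = delta) matches (v0, s0, c0). With v(u) = a u^3 + b u^4 + c u^5
# the endpoint conditions hold identically; solve 3 x 3 for the boundary.
quintic_extension <- function(v0, s0, c0, delta, u) {
  A <- rbind(
    c(delta^3, delta^4, delta^5),
    c(3 * delta^2, 4 * delta^3, 5 * delta^4),
    c(6 * delta, 12 * delta^2, 20 * delta^3)
  )
  abc <- solve(A, c(v0, s0, c0))
  abc[1L] * u^3 + abc[2L] * u^4 + abc[3L] * u^5
}

# Where the decaying tail reaches zero, from a quadratic continuation of
# sqrt(speed) at the boundary (w0, outward slope sw0, curvature cw0). A
# profile reaching zero speed with zero slope is locally parabolic, making
# sqrt(v) locally polynomial in the remaining time; its quadratic continuation
# crosses zero at the movement endpoint (exactly so for a minimum-jerk tail).
# Returns the outward distance, capped.
zero_crossing_distance <- function(w0, sw0, cw0, s0, v0, cap = 0.25) {
  roots <- numeric(0)
  if (abs(cw0) > 1e-12) {
    disc <- sw0^2 - 2 * cw0 * w0
    if (disc >= 0) {
      r <- (-sw0 + c(-1, 1) * sqrt(disc)) / cw0
      roots <- r[r > 0]
    }
  }
  if (length(roots) == 0L && sw0 < 0) roots <- -w0 / sw0
  # sqrt continuation unusable; linear crossing of the raw slope
  if (length(roots) == 0L && s0 < 0) roots <- -v0 / s0
  if (length(roots) == 0L) return(cap)
  min(min(roots), cap)
}

#' Extrapolate the segmented speed profile to zero
#'
#' Each side of the segment is extended by a quintic polynomial matching
#' speed, slope and curvature at the segment boundary and reaching zero speed
#' with zero slope (and curvature) at the new endpoint. The endpoint is placed
#' where the locally linear trend of sqrt(speed) reaches zero (exact for a
#' profile that approaches zero speed parabolically, as a smooth movement
#' does), at most 0.25 s beyond the boundary; the extension is clipped at
#' zero. If the profile is
#' still rising at the stop boundary (or falling at the start), that side
#' falls back to a linear-to-zero ramp with a warning.
#'
#' @param seg A `movement_segment` from [detect_segment()].
#' @param signals The `kinematic_signals` the segment was detected on.
#' @param max_extension_s Cap on the per-side extension (seconds).
#' @return The segment with `extrapolated_time_s` / `extrapolated_speed_deg_s`
#'   filled in (endpoints exactly zero).
#' @export
extrapolate_speed <- function(seg, signals, max_extension_s = 0.25) {
  stopifnot(inherits(seg, "movement_segment"), inherits(signals, "kinematic_signals"))
  tt <- signals$grid$time_s
  v <- signals$grid$angular_speed_deg_s
  dt <- tt[2L] - tt[1L]
  i0 <- seg$start_idx; i1 <- seg$stop_idx
  side <- function(i, dir) {
    # dir = -1: extend before start; dir = +1: extend after stop.
    v0 <- v[i]
    if (v0 <= 0) return(list(has = FALSE, t = numeric(0), v = numeric(0)))
    # grid slope/curvature at the boundary (central differences)
    s_grid <- (v[i + 1L] - v[i - 1L]) / (2 * dt)
    c_grid <- (v[i + 1L] - 2 * v[i] + v[i - 1L]) / dt^2
    w <- sqrt(pmax(v[(i - 1L):(i + 1L)], 0))
    sw_grid <- (w[3L] - w[1L]) / (2 * dt)
    cw_grid <- (w[3L] - 2 * w[2L] + w[1L]) / dt^2
    s_out <- dir * s_grid      # slope along the outward direction
    if (s_out >= 0) {
      warning("speed not decaying at segment boundary; linear-to-zero fallback")
      delta <- min(max_extension_s, v0 / max(abs(s_grid), v0 / max_extension_s))
      delta <- max(delta, dt)
      u <- seq_len(floor(delta / dt - 0.5)) * dt
      v_ext <- v0 * u / delta
    } else {
      delta <- zero_crossing_distance(w[2L], dir * sw_grid, cw_grid, s_out, v0,
                                      cap = max_extension_s)
      delta <- max(delta, dt)
      u <- seq_len(floor(delta / dt - 0.5)) * dt
      # along u (endpoint -> boundary) the boundary slope is -s_out
      v_ext <- pmax(quintic_extension(v0, -s_out, c_grid, delta, u), 0)
    }
    if (dir < 0) {
      list(has = TRUE, t = tt[i] - delta + u, v = v_ext, endpoint_t = tt[i] - delta)
    } else {
      list(has = TRUE, t = tt[i] + delta - rev(u), v = rev(v_ext),
           endpoint_t = tt[i] + delta)
    }
  }
  left <- side(i0, -1)
  right <- side(i1, +1)
  ext_t <- c(
    if (left$has) left$endpoint_t, left$t, tt[i0:i1], right$t,
    if (right$has) right$endpoint_t
  )
  ext_v <- c(
    if (left$has) 0, left$v, v[i0:i1], right$v,
    if (right$has) 0
  )
  seg$extrapolated_time_s <- ext_t
  seg$extrapolated_speed_deg_s <- pmax(ext_v, 0)
  seg
}

#' @export
print.movement_segment <- function(x, ...) {
  cat(sprintf(
    "<movement_segment> grid samples %d..%d, peak %.0f deg/s (threshold %.1f)%s\n",
    x$start_idx, x$stop_idx, x$peak_speed_deg_s, x$threshold_deg_s,
    if (is.null(x$extrapolated_time_s)) "" else ", extrapolated"
  ))
  invisible(x)
}
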