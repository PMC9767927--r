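# Track quantification: velocity, helix and polarization pitches, supertwist
# correction, cross-correlation, yaw-direction inference and the significance
# tests used to summarise populations of tracks.

#' Microtubule supertwist pitches by protofilament number
#'
#' Supertwist pitch of the protofilament lattice (um) for 12-, 13- and
#' 14-protofilament microtubules; positive values denote a left-handed helix.
#'
#' @param n_protofilaments 12, 13 or 14.
#' @return supertwist pitch (um, signed).
#' @export
supertwist_pitch <- function(n_protofilaments) {
  tab <- c(`12` = -3.4, `13` = -24.8, `14` = 6.8)
  key <- as.character(n_protofilaments)
  if (any(!key %in% names(tab)))
    stop("supertwist table covers 12-14 protofilaments only")
  unname(tab[key])
}

#' Fit the forward velocity of a track
#'
#' Least-squares slope of the longitudinal displacement (X) against time.
#'
#' @param track a track data.frame with \code{t} and \code{x_um}.
#' @return velocity (um/s).
#' @export
fit_velocity <- function(track) {
  ok <- is.finite(track$x_um)
  if (sum(ok) < 10) stop("need >= 10 frames to fit a velocity")
  unname(stats::coef(stats::lm(x_um ~ t, data = track[ok, ]))[2])
}

#' Detect oscillation cycles by same-sign zero crossings
#'
#' Smooths the series (centred moving average), removes its mean, and places
#' cycle boundaries at successive upward zero crossings. Partial cycles at
#' the ends are discarded by construction.
#'
#' @param series numeric oscillating series.
#' @param t time axis (same length).
#' @param smooth_window moving-average window (frames, odd; default 15; use
#'   1 to disable).
#' @param center reference level for the crossings: subtract the
#'   \code{"mean"} (default), remove a \code{"linear"} trend (for drifting
#'   baselines), or \code{"none"} for signed series whose natural level is
#'   zero (such as the DOP).
#' @return a data.frame with one row per full cycle: \code{start_t},
#'   \code{end_t}, \code{start_i}, \code{end_i} (indices); zero rows if less
#'   than one full cycle is present.
#' @export
detect_cycles <- function(series, t, smooth_window = 15,
                          center = c("mean", "linear", "none")) {
  stopifnot(length(series) == length(t))
  center <- match.arg(center)
  s <- if (smooth_window > 1) moving_average(series, smooth_window) else series
  ok <- is.finite(s)
  if (center == "linear" && sum(ok) > 2) {
    fit <- stats::lm.fit(cbind(1, t[ok]), s[ok])
    s[ok] <- fit$residuals
  } else if (center == "mean") {
    s <- s - mean(s[ok])
  }
  up <- which(ok[-length(s)] & ok[-1] & s[-length(s)] < 0 & s[-1] >= 0)
  # hysteresis: a boundary only counts once the series has dipped clearly
  # below the level since the previous one (rejects noise double-crossings)
  if (length(up) > 1) {
    hyst <- 0.25 * stats::sd(s[ok])
    keep <- up[1]
    for (j in up[-1]) {
      seg <- s[(keep[length(keep)] + 1):j]
      if (any(seg <= -hyst, na.rm = TRUE)) keep <- c(keep, j)
    }
    up <- keep
  }
  if (length(up) < 2)
    return(data.frame(start_t = numeric(0), end_t = numeric(0),
                      start_i = integer(0), end_i = integer(0)))
  # linear interpolation of the crossing time
  cross_t <- t[up] + (t[up + 1] - t[up]) * (-s[up]) / (s[up + 1] - s[up])
  data.frame(start_t = cross_t[-length(cross_t)], end_t = cross_t[-1],
             start_i = up[-length(up)], end_i = up[-1])
}

.pitch_from_cycles <- function(track, cycles) {
  if (nrow(cycles) == 0)
    return(structure(list(cycles = cycles, mean = NA_real_, sd = NA_real_,
                          n = 0L), class = "pitch_measurement"))
  x_at <- function(tt) stats::approx(track$t, track$x_um, xout = tt,
                                     rule = 2)$y
  dx <- x_at(cycles$end_t) - x_at(cycles$start_t)
  cycles$x_displacement_um <- dx
  structure(list(cycles = cycles, mean = mean(dx), sd = stats::sd(dx),
                 n = nrow(cycles)), class = "pitch_measurement")
}

#' @export
print.pitch_measurement <- function(x, ...) {
  cat(sprintf("pitch: %.3f +/- %.3f um (n = %d cycles)\n",
              x$mean, ifelse(is.na(x$sd), 0, x$sd), x$n))
  invisible(x)
}

#' Helix pitch of a track
#'
#' X displacement per full period of the Y oscillation (one orbit of the
#' cargo around the microtubule), one value per detected cycle.
#'
#' @param track a track data.frame.
#' @param smooth_window passed to [detect_cycles()].
#' @return a \code{pitch_measurement}: per-cycle table, mean, sd, n.
#' @export
helix_pitch <- function(track, smooth_window = 15) {
  cyc <- detect_cycles(track$y_um, track$t, smooth_window)
  .pitch_from_cycles(track, cyc)
}

#' Polarization pitch of a track
#'
#' X displacement per full period of the polarization signal, i.e. per 180
#' degrees of in-plane angle. The angle series is unwrapped and smoothed;
#' when it carries a net rotation the cycle boundaries are its crossings of
#' the mid-levels (start + 90 + 180 k degrees), which lie far from the
#' plateau wobble of the coupled-rotation trace and are therefore crossed
#' once per half-turn; for an oscillatory trace (net rotation under half a
#' turn) the boundaries fall back to oscillation cycles of
#' \code{cos(2 theta)}. The DOP may substitute as the cycle signal when the
#' angle is undefined over part of the track.
#'
#' @param track a track data.frame with \code{angle_deg} (or \code{dop} when
#'   \code{signal = "dop"}).
#' @param signal \code{"angle"} (default) or \code{"dop"}.
#' @param smooth_window smoothing window (frames, odd; default 15).
#' @return a \code{pitch_measurement}.
#' @export
polarization_pitch <- function(track, signal = c("angle", "dop"),
                               smooth_window = 15) {
  signal <- match.arg(signal)
  if (signal == "dop") {
    # the DOP changes sign with cos(2(theta + zeta - eta)): its natural
    # crossing level is zero, once upward per half-turn
    cyc <- detect_cycles(track$dop, track$t, smooth_window, center = "none")
    return(.pitch_from_cycles(track, cyc))
  }
  if (all(is.na(track$angle_deg)))
    stop("track has no angle estimates; run estimate_angle_series() first")
  ang <- unwrap_angle(track$angle_deg, period = 180)
  sm <- if (smooth_window > 1) moving_average(ang, smooth_window) else ang
  ok <- which(is.finite(sm))
  if (length(ok) < 2) return(.pitch_from_cycles(track, detect_cycles(
    numeric(0), numeric(0), 1)))
  net <- sm[ok[length(ok)]] - sm[ok[1]]
  if (abs(net) < 135) {
    cyc <- detect_cycles(cos(2 * sm * pi / 180), track$t, 1)
    return(.pitch_from_cycles(track, cyc))
  }
  dir <- sign(net)
  a0 <- sm[ok[1]]
  levels <- seq(a0 + dir * 90, sm[ok[length(ok)]] - dir * 45, by = dir * 180)
  cross_t <- vapply(levels, function(L) {
    s <- dir * (sm - L)
    i <- which(is.finite(s[-length(s)]) & is.finite(s[-1]) &
                 s[-length(s)] < 0 & s[-1] >= 0)
    if (length(i) == 0) return(NA_real_)
    tt <- track$t[i] + (track$t[i + 1] - track$t[i]) *
      (-s[i]) / (s[i + 1] - s[i])
    mean(tt)     # wobble re-crossings of a level cluster tightly: average them
  }, 0)
  cross_t <- cross_t[is.finite(cross_t)]
  if (length(cross_t) < 2 || is.unsorted(cross_t))
    return(.pitch_from_cycles(track, data.frame(
      start_t = numeric(0), end_t = numeric(0),
      start_i = integer(0), end_i = integer(0))))
  cyc <- data.frame(start_t = cross_t[-length(cross_t)], end_t = cross_t[-1],
                    start_i = NA_integer_, end_i = NA_integer_)
  .pitch_from_cycles(track, cyc)
}

#' Supertwist correction of a measured pitch
#'
#' The measured helix pitch combines the motor-generated pitch and the
#' microtubule supertwist through reciprocal addition,
#' \code{1/P_measured = 1/P_motor + 1/P_mt}; this inverts it:
#' \code{P_motor = 1 / (1/P_measured - 1/P_mt)}. Signs follow the
#' left-handed-positive convention. Pass \code{p_mt = Inf} for an idealised
#' straight 13-protofilament lattice (no supertwist).
#'
#' @param p_measured measured pitch (um, signed, nonzero).
#' @param p_mt microtubule supertwist pitch (um, signed, nonzero; may be
#'   \code{Inf}); see [supertwist_pitch()].
#' @return motor pitch (um, signed).
#' @export
correct_pitch <- function(p_measured, p_mt) {
  stopifnot(all(p_measured != 0), all(p_mt != 0),
            all(is.infinite(p_mt) | p_measured != p_mt))
  1 / (1 / p_measured - 1 / p_mt)
}

#' Pearson-normalized cross-correlation function
#'
#' CCF between two equal-length series over lags \code{-max_lag..max_lag},
#' computed as the Pearson correlation of the overlapping segments at each
#' lag (both segments re-centred and re-scaled per lag). Positive lag means
#' \code{b} is delayed relative to \code{a}.
#'
#' @param a,b numeric series of equal length.
#' @param max_lag maximum lag (frames).
#' @return a data.frame with \code{lag} and \code{ccf}; \code{ccf} is
#'   \code{NA} at lags where either segment is constant.
#' @export
cross_correlation <- function(a, b, max_lag) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  stopifnot(max_lag < n - 1)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      ai <- a[1:(n - k)]; bi <- b[(1 + k):n]
    } else {
      ai <- a[(1 - k):n]; bi <- b[1:(n + k)]
    }
    ok <- is.finite(ai) & is.finite(bi)
    if (sum(ok) < 3 || stats::sd(ai[ok]) == 0 || stats::sd(bi[ok]) == 0)
      return(NA_real_)
    stats::cor(ai[ok], bi[ok])
  }, 0)
  data.frame(lag = lags, ccf = cc)
}

#' Infer the yaw direction of a track from the Y--angle correlation
#'
#' Pearson correlation between the Y displacement and the in-plane angle
#' series determines the yaw sense: negative for clockwise yawing, positive
#' for counterclockwise. The angle series is unwrapped (180-degree period)
#' and linearly detrended before correlating, which removes the net-rotation
#' ramp and leaves the orbit-locked modulation whose phase encodes the yaw
#' direction at every initial phase angle.
#'
#' @param track a track data.frame with \code{y_um} and \code{angle_deg}.
#' @param r_min threshold on |r| below which the direction is
#'   \code{"undetermined"} (default 0.3).
#' @return a list with \code{pearson_r} and \code{direction} in
#'   \code{c("cw", "ccw", "undetermined")}.
#' @export
yaw_direction <- function(track, r_min = 0.3) {
  if (all(is.na(track$angle_deg)))
    stop("track has no angle estimates; run estimate_angle_series() first")
  ang <- unwrap_angle(track$angle_deg, period = 180)
  ok <- is.finite(ang) & is.finite(track$y_um)
  fit <- stats::lm.fit(cbind(1, track$t[ok]), ang[ok])
  r <- stats::cor(track$y_um[ok], fit$residuals)
  dir <- if (!is.finite(r)) "undetermined"
  else if (r < -r_min) "cw"
  else if (r > r_min) "ccw"
  else "undetermined"
  list(pearson_r = r, direction = dir)
}

#' Exact two-sided binomial test of equal yaw probabilities
#'
#' Tests the observed clockwise count against the null that clockwise and
#' counterclockwise yawing are equally likely, by doubling the smaller exact
#' tail probability (capped at 1).
#'
#' @param n_cw clockwise count.
#' @param n_total total count, > 0.
#' @return two-sided p value.
#' @export
binomial_direction_test <- function(n_cw, n_total) {
  stopifnot(n_total > 0, n_cw >= 0, n_cw <= n_total)
  lo <- sum(stats::dbinom(0:n_cw, n_total, 0.5))
  hi <- sum(stats::dbinom(n_cw:n_total, n_total, 0.5))
  min(1, 2 * min(lo, hi))
}

#' Welch's two-sided t test
#'
#' Unequal-variance two-sample t test (Welch--Satterthwaite degrees of
#' freedom), as used to compare velocities and pitches between motor
#' constructs.
#'
#' @param sample_a,sample_b numeric samples, each of length >= 2.
#' @return two-sided p value.
#' @export
welch_test <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) return(1)
    stop("zero variance in both samples")
  }
  stats::t.test(sample_a, sample_b, var.equal = FALSE)$p.value
}

#' Full per-track analysis report
#'
#' Runs the standard quantification on one track: angle estimation (if
#' absent), velocity, helix and polarization pitches, yaw direction and the
#' Y--polarization cross-correlation peak.
#'
#' @param track a track data.frame (noisy observation).
#' @param cal a [polar_calibration] used to estimate angles when the track
#'   has none.
#' @param smooth_window smoothing for cycle detection (default 15).
#' @param max_lag_s CCF half-width in seconds (default 2).
#' @return a list of class \code{track_report}: \code{velocity_um_s},
#'   \code{helix_pitch}, \code{polarization_pitch} (both
#'   \code{pitch_measurement}), \code{pearson_r}, \code{direction},
#'   \code{ccf} (data.frame) and the analysed \code{track} (with angles).
#' @export
analyze_track <- function(track, cal = NULL, smooth_window = 15,
                          max_lag_s = 2) {
  if (all(is.na(track$angle_deg))) {
    if (is.null(cal)) stop("track has no angles and no calibration given")
    est <- estimate_angle_series(track$i_bottom, track$i_upper, cal)
    track$angle_deg <- est$angle_deg
    track$angle_defined <- as.integer(est$defined)
  }
  frame_rate <- 1 / stats::median(diff(track$t))
  max_lag <- min(round(max_lag_s * frame_rate), nrow(track) - 2)
  yd <- yaw_direction(track)
  structure(list(
    velocity_um_s = fit_velocity(track),
    helix_pitch = helix_pitch(track, smooth_window),
    polarization_pitch = polarization_pitch(track,
                                            smooth_window = smooth_window),
    pearson_r = yd$pearson_r,
    direction = yd$direction,
    ccf = cross_correlation(track$y_um, track$dop, max_lag),
    track = track), class = "track_report")
}

#' @export
print.track_report <- function(x, ...) {
  cat(sprintf("velocity: %.3f um/s\n", x$velocity_um_s))
  cat("helix "); print(x$helix_pitch)
  cat("polarization "); print(x$polarization_pitch)
  cat(sprintf("yaw: %s (Pearson r = %.2f)\n", x$direction, x$pearson_r))
  invisible(x)
}
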