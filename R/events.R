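#' Detect ground contact from the optoelectronic LED status
#'
#' Initial contact is the time of the first off-to-on transition of the
#' diode-interruption status after `search_from`.
#'
#' @param led a [led_series()].
#' @param search_from earliest time (s) at which a transition counts.
#' @return contact time, seconds.
#' @export
#' @examples
#' led <- led_series(seq(0, 0.03, by = 0.01), c(FALSE, FALSE, TRUE, TRUE))
#' detect_contact(led) # 0.02
detect_contact <- function(led, search_from = 0) {
  on <- led$on
  trans <- which(!on[-length(on)] & on[-1]) + 1
  trans <- trans[led$time_s[trans] >= search_from]
  if (length(trans) == 0) {
    abort_swayrisk("no off->on LED transition after search_from",
                   class = "swayrisk_event_error")
  }
  led$time_s[trans[1]]
}

# zero-phase low-pass (4th-order Butterworth, filtfilt); falls back to the
# raw series when the window is too short for stable edge padding
lowpass_zero_phase <- function(x, fs, cutoff_hz) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) return(x)
  if (length(x) < 24) return(x)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Stabilization time after landing
#'
#' The leg is considered stable at the first strict local minimum of the
#' rectified shank angular-velocity magnitude after ground contact; the
#' stabilization time Ts is that instant minus the contact time. The
#' magnitude (Euclidean norm of the three gyro channels) is smoothed with a
#' zero-phase 4th-order Butterworth low-pass before the minimum search, since
#' the raw rectified signal is minima-ridden; plateaus resolve to their
#' earliest sample.
#'
#' @param trial the landing [imu_trial()].
#' @param t_contact contact time from [detect_contact()], seconds.
#' @param cutoff_hz low-pass cutoff for the smoothed magnitude.
#' @return Ts in seconds.
#' @export
stabilization_time <- function(trial, t_contact, cutoff_hz = 10) {
  trial <- validate_imu_trial(trial)
  if (max(trial$time_s) - t_contact < 0.05) {
    abort_swayrisk("need at least 0.05 s of data after contact",
                   class = "swayrisk_event_error")
  }
  fs <- trial_rate(trial)
  wmag <- sqrt(rowSums(trial_gyro(trial)^2))
  wmag <- lowpass_zero_phase(wmag, fs, cutoff_hz)
  # the zero-phase filter rings near the series end; minima inside its edge
  # region are artefacts, not stabilization
  t_guard <- max(trial$time_s) - 0.12
  after <- which(trial$time_s > t_contact & trial$time_s <= t_guard)
  # strict local minimum: lower than both neighbours; plateaus -> first sample
  idx <- NA_integer_
  for (k in after) {
    if (k <= 1 || k >= length(wmag)) next
    left <- wmag[k - 1]
    j <- k
    while (j < length(wmag) && wmag[j + 1] == wmag[k]) j <- j + 1
    if (j >= length(wmag)) break
    if (wmag[k] < left && wmag[k] < wmag[j + 1]) { idx <- k; break }
  }
  if (is.na(idx)) {
    abort_swayrisk("no local minimum of |angular velocity| before end of trial",
                   class = "swayrisk_event_error")
  }
  trial$time_s[idx] - t_contact
}

# right-aligned rolling SD over a window of `w` samples (NA until filled)
rolling_sd <- function(x, w) {
  n <- length(x)
  if (w < 2 || n < w) return(rep(NA_real_, n))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  out <- rep(NA_real_, n)
  i <- w:n
  s <- cs[i + 1] - cs[i + 1 - w]
  s2 <- cs2[i + 1] - cs2[i + 1 - w]
  v <- (s2 - s^2 / w) / (w - 1)
  out[i] <- sqrt(pmax(v, 0))
  out
}

#' Single-leg-squat descent window
#'
#' Movement start is the first instant at which the rolling standard
#' deviation of the magnitude of the three orientation angles exceeds `k`
#' times the average of the same rolling SD on the static trial. Movement
#' end is the maximum of the angle about the y axis (approximately the knee
#' flexion axis) after the start; `theta_ymax` is its value and the descent
#' duration is `T_DP = t_end - t_start`. The rolling SD is evaluated at
#' every sample over a trailing window (`win_s`), so the detected start has
#' sample-level resolution.
#'
#' @param orient `orientation_series` of the squat trial.
#' @param static_orient `orientation_series` of the static trial (>= 1 s).
#' @param k threshold multiplier on the static baseline (the five-times rule).
#' @param win_s rolling-window length in seconds.
#' @return a tibble with columns `t_start`, `t_end`, `theta_ymax`, `t_dp`.
#' @export
sls_window <- function(orient, static_orient, k = 5.0, win_s = 0.5) {
  if (diff(range(static_orient$time_s)) < 1 - 1e-9) {
    abort_swayrisk("static series must cover at least 1 s")
  }
  fs <- 1 / stats::median(diff(orient$time_s))
  w <- max(2L, as.integer(round(win_s * fs)))
  ang_mag <- function(o) sqrt(o$theta_x^2 + o$theta_y^2 + o$theta_z^2)
  base_sd <- rolling_sd(ang_mag(static_orient), w)
  baseline <- mean(base_sd, na.rm = TRUE)
  mov_sd <- rolling_sd(ang_mag(orient), w)
  # guard: an exactly-zero baseline (noise-free synthetic static) still needs
  # a positive threshold for "overcame"
  thr <- k * baseline
  cross <- which(!is.na(mov_sd) & mov_sd > thr & mov_sd > 1e-12)
  if (length(cross) == 0) {
    abort_swayrisk("movement threshold never crossed",
                   class = "swayrisk_event_error")
  }
  i_start <- cross[1]
  t_start <- orient$time_s[i_start]
  after <- seq(i_start, nrow(orient))
  i_end <- after[which.max(orient$theta_y[after])]
  if (i_end >= nrow(orient)) {
    abort_swayrisk("theta_y maximum at the final sample: truncated descent",
                   class = "swayrisk_event_error")
  }
  tibble(
    t_start = t_start,
    t_end = orient$time_s[i_end],
    theta_ymax = orient$theta_y[i_end],
    t_dp = orient$time_s[i_end] - t_start
  )
}
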