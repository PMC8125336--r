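# canonical feature order (13 features: 7 mCMJ + 6 SLS)
#' Names of the 13 features, in canonical order
#'
#' mCMJ: stabilization time, path lengths, ellipse area and the two
#' load-absorption RMS indices; SLS: descent duration, path lengths, ellipse
#' area and the peak knee-flexion-axis angle. All sway and RMS quantities are
#' time-normalized by Ts (mCMJ) or T_DP (SLS).
#'
#' @return character vector of length 13.
#' @export
acl_feature_names <- function() {
  c("mcmj_ts", "mcmj_pl", "mcmj_pl_ap", "mcmj_pl_ml", "mcmj_ea",
    "mcmj_rms_z", "mcmj_rms_xy",
    "sls_t_dp", "sls_pl", "sls_pl_ap", "sls_pl_ml", "sls_ea",
    "sls_theta_ymax")
}

path_window <- function(path, window = NULL) {
  if (is.null(window)) return(path)
  dplyr::filter(path, .data$time_s >= window[1] - 1e-9,
                .data$time_s <= window[2] + 1e-9)
}

#' Prieto sway path lengths
#'
#' Total, antero-posterior and medio-lateral path lengths of a sway trace:
#' `PL = sum(sqrt(dx^2 + dy^2))`, `PL_ML = sum(|dx|)`, `PL_AP = sum(|dy|)`
#' over consecutive in-window samples, in cm.
#'
#' @param path a `sway_path` from [project_vertical_axis()].
#' @param window optional `c(t0, t1)` time window, seconds.
#' @return tibble with columns `pl`, `pl_ap`, `pl_ml`.
#' @export
#' @examples
#' p <- structure(tibble::tibble(time_s = 0:3 / 100,
#'                               ml_cm = c(0, 1, 1, 0),
#'                               ap_cm = c(0, 0, 1, 1)),
#'                class = c("sway_path", "tbl_df", "tbl", "data.frame"))
#' path_lengths(p) # PL = 3, PL_ML = 2, PL_AP = 1
path_lengths <- function(path, window = NULL) {
  p <- path_window(path, window)
  if (nrow(p) < 2) {
    abort_swayrisk("need at least 2 samples in window for path lengths")
  }
  dx <- diff(p$ml_cm); dy <- diff(p$ap_cm)
  tibble(pl = sum(sqrt(dx^2 + dy^2)), pl_ap = sum(abs(dy)),
         pl_ml = sum(abs(dx)))
}

#' Bivariate confidence-ellipse parameters and area
#'
#' Prieto's confidence-ellipse construction: with sample variances `s_x^2`,
#' `s_y^2` and covariance `s_xy` over the window, the ellipse covering the
#' requested fraction of points has area
#' `EA = 2 * pi * F(level; 2, n-2) * sqrt(s_x^2 s_y^2 - s_xy^2)` (cm^2).
#' `ellipse_params()` additionally returns the centre, covariance and the
#' Mahalanobis radius-squared `r2 = 2 * F`, so that a point `p` lies inside
#' the ellipse iff `(p - mu)' S^{-1} (p - mu) <= r2`.
#'
#' @param path a `sway_path`.
#' @param window optional time window, seconds.
#' @param level coverage level of the ellipse (0.99 for the 99% ellipse).
#' @return `ellipse_area()`: the area in cm^2 (0 with a warning for a
#'   degenerate, collinear cloud). `ellipse_params()`: a list with `center`,
#'   `cov`, `r2`, `area`, `n`.
#' @export
ellipse_area <- function(path, window = NULL, level = 0.99) {
  ellipse_params(path, window, level)$area
}

#' @rdname ellipse_area
#' @export
ellipse_params <- function(path, window = NULL, level = 0.99) {
  p <- path_window(path, window)
  n <- nrow(p)
  if (n < 3) abort_swayrisk("need at least 3 points for an ellipse")
  sxx <- stats::var(p$ml_cm)
  syy <- stats::var(p$ap_cm)
  sxy <- stats::cov(p$ml_cm, p$ap_cm)
  det <- sxx * syy - sxy^2
  f <- stats::qf(level, 2, n - 2)
  if (det <= 0 || !is.finite(det)) {
    if (det < -1e-9 * max(sxx * syy, 1e-300)) {
      # numerically negative determinant beyond rounding
      det <- 0
    }
    warning("degenerate (collinear) sway cloud: ellipse area set to 0")
    return(list(center = c(mean(p$ml_cm), mean(p$ap_cm)),
                cov = matrix(c(sxx, sxy, sxy, syy), 2, 2),
                r2 = 2 * f, area = 0, n = n))
  }
  list(
    center = c(mean(p$ml_cm), mean(p$ap_cm)),
    cov = matrix(c(sxx, sxy, sxy, syy), 2, 2),
    r2 = 2 * f,
    area = 2 * pi * f * sqrt(det),
    n = n
  )
}

#' @importFrom stats cov
NULL

#' Load-absorption RMS indices over the landing window
#'
#' Acceleration is rotated into the absolute frame with the estimated
#' orientation, gravity (9.81 m/s^2) is subtracted from the vertical channel,
#' and the RMS of the vertical component (`rms_z`) and of the horizontal
#' module (`rms_xy`) are computed over `[t_contact, t_contact + ts]` and
#' divided by Ts. Gravity removal happens in the absolute frame; otherwise
#' the vertical RMS is dominated by the constant 9.81 offset and the group
#' contrast vanishes.
#'
#' @param trial the landing [imu_trial()].
#' @param orient matching `orientation_series` (same clock).
#' @param t_contact contact time, s.
#' @param ts stabilization time, s.
#' @return tibble with `rms_z`, `rms_xy` on the Ts-normalized scale.
#' @export
rms_load <- function(trial, orient, t_contact, ts) {
  idx <- which(trial$time_s >= t_contact - 1e-9 &
                 trial$time_s <= t_contact + ts + 1e-9)
  if (length(idx) == 0) abort_swayrisk("empty landing window")
  if (ts <= 0) abort_swayrisk("ts must be positive")
  accel <- trial_accel(trial)
  a_world <- matrix(0, length(idx), 3)
  for (j in seq_along(idx)) {
    k <- idx[j]
    R <- quat_to_matrix(c(orient$qw[k], orient$qx[k], orient$qy[k], orient$qz[k]))
    a_world[j, ] <- R %*% accel[k, ]
  }
  a_world[, 3] <- a_world[, 3] - GRAVITY
  tibble(
    rms_z = sqrt(mean(a_world[, 3]^2)) / ts,
    rms_xy = sqrt(mean(a_world[, 1]^2 + a_world[, 2]^2)) / ts
  )
}

#' Time-normalize stability parameters
#'
#' Divides each sway parameter by the window duration (Ts for the jump,
#' T_DP for the squat).
#'
#' @param params tibble with columns `pl`, `pl_ap`, `pl_ml`, `ea` (raw, over
#'   the window).
#' @param duration window duration, seconds (> 0).
#' @return tibble with the same columns divided by `duration`.
#' @export
normalize_stability <- function(params, duration) {
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    abort_swayrisk("duration must be a positive scalar")
  }
  dplyr::mutate(params, across(all_of(intersect(
    c("pl", "pl_ap", "pl_ml", "ea"), names(params))), ~ .x / duration))
}

#' Extract the seven mCMJ features from one landing repetition
#'
#' Runs the full chain for one jump: Mahony orientation (re-aligned with the
#' static trial), LED contact detection, stabilization time, sway projection
#' and Prieto parameters over `[contact, contact + Ts]`, Ts-normalization,
#' and the load-absorption RMS indices.
#'
#' @param trial landing [imu_trial()].
#' @param led matching [led_series()].
#' @param static_trial upright calibration [imu_trial()].
#' @param search_from earliest admissible contact time, s.
#' @param level ellipse coverage level.
#' @param kp,ki,accel_gate,cutoff_hz tuning forwarded to
#'   [mahony_orientation()] and [stabilization_time()].
#' @param depth_cm projection-plane depth.
#' @return one-row tibble `mcmj_ts, mcmj_pl, mcmj_pl_ap, mcmj_pl_ml, mcmj_ea,
#'   mcmj_rms_z, mcmj_rms_xy`.
#' @export
extract_jump_features <- function(trial, led, static_trial, search_from = 0,
                                  level = 0.99, kp = 1.0, ki = 0.3,
                                  accel_gate = 0.4, cutoff_hz = 10,
                                  depth_cm = 1.0) {
  corr <- estimate_static_alignment(static_trial)
  orient <- mahony_orientation(trial, corr, kp = kp, ki = ki,
                               accel_gate = accel_gate)
  t_c <- detect_contact(led, search_from)
  ts <- stabilization_time(trial, t_c, cutoff_hz = cutoff_hz)
  win <- c(t_c, t_c + ts)
  sway <- project_vertical_axis(orient, depth_cm)
  stab <- path_lengths(sway, win)
  stab$ea <- ellipse_area(sway, win, level)
  stab <- normalize_stability(stab, ts)
  rms <- rms_load(trial, orient, t_c, ts)
  tibble(
    mcmj_ts = ts, mcmj_pl = stab$pl, mcmj_pl_ap = stab$pl_ap,
    mcmj_pl_ml = stab$pl_ml, mcmj_ea = stab$ea,
    mcmj_rms_z = rms$rms_z, mcmj_rms_xy = rms$rms_xy
  )
}

#' Extract the six SLS features from one squat repetition
#'
#' @param trial squat [imu_trial()].
#' @param static_trial upright calibration [imu_trial()].
#' @param level ellipse coverage level.
#' @param k,win_s forwarded to [sls_window()].
#' @param kp,ki,accel_gate forwarded to [mahony_orientation()].
#' @param depth_cm projection-plane depth.
#' @return one-row tibble `sls_t_dp, sls_pl, sls_pl_ap, sls_pl_ml, sls_ea,
#'   sls_theta_ymax`.
#' @export
extract_squat_features <- function(trial, static_trial, level = 0.99,
                                   k = 5.0, win_s = 0.5, kp = 1.0, ki = 0.3,
                                   accel_gate = 0.4, depth_cm = 1.0) {
  corr <- estimate_static_alignment(static_trial)
  orient <- mahony_orientation(trial, corr, kp = kp, ki = ki,
                               accel_gate = accel_gate)
  static_orient <- mahony_orientation(static_trial, corr, kp = kp, ki = ki,
                                      accel_gate = accel_gate)
  ev <- sls_window(orient, static_orient, k = k, win_s = win_s)
  win <- c(ev$t_start, ev$t_end)
  sway <- project_vertical_axis(orient, depth_cm)
  stab <- path_lengths(sway, win)
  stab$ea <- ellipse_area(sway, win, level)
  stab <- normalize_stability(stab, ev$t_dp)
  tibble(
    sls_t_dp = ev$t_dp, sls_pl = stab$pl, sls_pl_ap = stab$pl_ap,
    sls_pl_ml = stab$pl_ml, sls_ea = stab$ea,
    sls_theta_ymax = ev$theta_ymax
  )
}

#' Average per-repetition features into one athlete feature vector
#'
#' Arithmetic mean per feature across the five repetitions of each task,
#' returned in the canonical 13-feature order of [acl_feature_names()].
#'
#' @param mcmj_reps tibble of per-repetition mCMJ features (5 rows expected).
#' @param sls_reps tibble of per-repetition SLS features (5 rows expected).
#' @param allow_fewer allow fewer than 5 repetitions (with a warning).
#' @return one-row tibble with 13 feature columns.
#' @export
build_feature_vector <- function(mcmj_reps, sls_reps, allow_fewer = FALSE) {
  for (x in list(mcmj = mcmj_reps, sls = sls_reps)) {
    if (nrow(x) == 0) abort_swayrisk("zero repetitions supplied")
  }
  if (nrow(mcmj_reps) != 5 || nrow(sls_reps) != 5) {
    if (!allow_fewer && (nrow(mcmj_reps) < 5 || nrow(sls_reps) < 5)) {
      abort_swayrisk("expected 5 repetitions per task (set allow_fewer = TRUE)")
    }
    warning("feature vector averaged over a number of repetitions != 5")
  }
  means <- c(colMeans(as.data.frame(mcmj_reps)), colMeans(as.data.frame(sls_reps)))
  out <- as_tibble(as.list(means))[, acl_feature_names()]
  if (any(!is.finite(unlist(out)))) abort_swayrisk("non-finite feature value")
  out
}
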