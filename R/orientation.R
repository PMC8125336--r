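#' Static re-alignment from an upright calibration trial
#'
#' Estimates the fixed rotation that maps the sensor frame, as mounted during
#' quiet upright stance, onto the absolute (gravity-aligned) frame. The
#' rotation takes the time-averaged accelerometer vector onto (0, 0, +g) by
#' the shortest arc, so heading (rotation about gravity) is pinned to zero:
#' with a single 6-axis IMU yaw is unobservable, and the medio-lateral /
#' antero-posterior axis identity downstream relies on this convention.
#'
#' @param static an [imu_trial()] recorded during quiet upright stance,
#'   at least 1 s long.
#' @param max_gyro_dps stillness gate: mean gyro magnitude above this value
#'   (degrees/s) raises an error.
#' @return a 3x3 proper rotation matrix of class `rotation_correction`
#'   (determinant +1) mapping sensor-frame vectors to the absolute frame.
#' @export
#' @examples
#' still <- synthesize_static_trial(duration_s = 1.5, seed = 1)
#' estimate_static_alignment(still)
estimate_static_alignment <- function(static, max_gyro_dps = 5) {
  static <- validate_imu_trial(static)
  if (diff(range(static$time_s)) < 1 - 1e-9) {
    abort_swayrisk("static calibration trial must cover at least 1 s")
  }
  gmag <- sqrt(rowSums(trial_gyro(static)^2))
  if (mean(gmag) >= max_gyro_dps) {
    abort_swayrisk(sprintf(
      "movement detected during static trial: mean |gyro| = %.1f deg/s (limit %.1f)",
      mean(gmag), max_gyro_dps), class = "swayrisk_stillness_error")
  }
  a_mean <- colMeans(trial_accel(static))
  if (sqrt(sum(a_mean^2)) < 0.5 * GRAVITY) {
    abort_swayrisk("static trial accelerometer mean is far from gravity")
  }
  q <- quat_between(a_mean, c(0, 0, 1))
  R <- quat_to_matrix(q)
  structure(R, class = "rotation_correction")
}

#' Mahony complementary-filter orientation estimation
#'
#' Six-axis (accelerometer + gyroscope) Mahony filter: the gyroscope is
#' integrated on the unit-quaternion manifold while the accelerometer's
#' gravity direction corrects tilt drift through a proportional-integral
#' feedback term. The magnetometer is ignored, so heading is arbitrary and
#' fixed by the static re-alignment. Raw samples are first rotated by
#' `correction` (the re-alignment of the sensor axes with the absolute
#' frame), and the filter is initialised from the first-sample
#' accelerometer tilt with zero heading. The accelerometer correction is
#' gated off whenever the measured specific-force norm deviates from gravity
#' by more than `accel_gate` (relative), e.g. during flight or landing
#' impacts, where the accelerometer does not point along gravity.
#'
#' @param trial an [imu_trial()].
#' @param correction rotation from [estimate_static_alignment()] (identity if
#'   omitted).
#' @param kp,ki proportional and integral Mahony gains (1/s), both >= 0.
#' @param accel_gate relative band around g within which the accelerometer is
#'   trusted; set `Inf` to always apply the correction.
#' @return a tibble of class `orientation_series` with columns `time_s`,
#'   unit quaternion `qw, qx, qy, qz` (body -> absolute), the sensor vertical
#'   axis in the absolute frame `sx, sy, sz`, and intrinsic x-y-z angles
#'   `theta_x, theta_y, theta_z` in degrees (`theta_y` approximates the knee
#'   flexion axis, positive in squat flexion).
#' @export
mahony_orientation <- function(trial, correction = NULL, kp = 1.0, ki = 0.3,
                               accel_gate = 0.4) {
  trial <- validate_imu_trial(trial)
  if (kp < 0 || ki < 0) abort_swayrisk("Mahony gains must be nonnegative")
  accel <- trial_accel(trial)
  gyro <- trial_gyro(trial) * pi / 180
  if (!all(is.finite(accel)) || !all(is.finite(gyro))) {
    abort_swayrisk("non-finite samples in trial")
  }
  if (!is.null(correction)) {
    C <- unclass(correction)
    accel <- accel %*% t(C)
    gyro <- gyro %*% t(C)
  }
  n <- nrow(accel)
  tt <- trial$time_s

  # initial tilt from the first accelerometer sample, zero heading
  a0 <- accel[1, ]
  q <- if (sqrt(sum(a0^2)) > 0.5 * GRAVITY) {
    quat_conjugate(quat_between(a0, c(0, 0, 1)))
  } else {
    c(1, 0, 0, 0)
  }

  quat <- matrix(0, n, 4)
  saxis <- matrix(0, n, 3)
  theta <- matrix(0, n, 3)
  integral <- c(0, 0, 0)

  for (k in seq_len(n)) {
    if (k > 1) {
      dt <- tt[k] - tt[k - 1]
      a <- accel[k, ]
      anorm <- sqrt(sum(a^2))
      err <- c(0, 0, 0)
      if (is.finite(accel_gate)) {
        use_acc <- anorm > 1e-9 && abs(anorm - GRAVITY) < accel_gate * GRAVITY
      } else {
        use_acc <- anorm > 1e-9
      }
      if (use_acc) {
        v_meas <- a / anorm
        # gravity direction in body frame predicted by current estimate
        R <- quat_to_matrix(q)
        v_pred <- c(R[3, 1], R[3, 2], R[3, 3])
        err <- c(
          v_meas[2] * v_pred[3] - v_meas[3] * v_pred[2],
          v_meas[3] * v_pred[1] - v_meas[1] * v_pred[3],
          v_meas[1] * v_pred[2] - v_meas[2] * v_pred[1]
        )
      }
      integral <- integral + ki * err * dt
      omega <- gyro[k, ] + kp * err + integral
      q <- quat_normalize(quat_multiply(q, quat_from_rotvec(omega * dt)))
    }
    quat[k, ] <- q
    R <- quat_to_matrix(q)
    saxis[k, ] <- R[, 3]
    theta[k, ] <- rotmat_to_xyz_deg(R)
  }

  out <- tibble(
    time_s = tt,
    qw = quat[, 1], qx = quat[, 2], qy = quat[, 3], qz = quat[, 4],
    sx = saxis[, 1], sy = saxis[, 2], sz = saxis[, 3],
    theta_x = theta[, 1], theta_y = theta[, 2], theta_z = theta[, 3]
  )
  class(out) <- c("orientation_series", class(out))
  out
}

# exact orientation series from a known body->world rotation sequence
# (used by the generator and by closed-form tests)
orientation_series_from_quat <- function(time_s, quat) {
  n <- length(time_s)
  saxis <- matrix(0, n, 3); theta <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    R <- quat_to_matrix(quat[k, ])
    saxis[k, ] <- R[, 3]
    theta[k, ] <- rotmat_to_xyz_deg(R)
  }
  out <- tibble(
    time_s = time_s,
    qw = quat[, 1], qx = quat[, 2], qy = quat[, 3], qz = quat[, 4],
    sx = saxis[, 1], sy = saxis[, 2], sz = saxis[, 3],
    theta_x = theta[, 1], theta_y = theta[, 2], theta_z = theta[, 3]
  )
  class(out) <- c("orientation_series", class(out))
  out
}

#' Project the sensor vertical axis onto the plane 1 cm below the sensor
#'
#' The sway trace is the intersection of the line through the sensor origin
#' along its vertical axis S with the horizontal plane `depth_cm` below the
#' origin: `xy = -depth_cm * (sx/sz, sy/sz)`, in centimetres. Line-plane
#' intersection (rather than orthogonal projection) reproduces the
#' "1 cm below the sensor" geometry and reduces to small-angle
#' proportionality.
#'
#' @param orient an `orientation_series` from [mahony_orientation()].
#' @param depth_cm depth of the projection plane below the sensor, cm.
#' @return a tibble of class `sway_path` with columns `time_s`, `ml_cm`
#'   (medio-lateral, x) and `ap_cm` (antero-posterior, y).
#' @export
project_vertical_axis <- function(orient, depth_cm = 1.0) {
  bad <- which(orient$sz <= 0.1)
  if (length(bad) > 0) {
    abort_swayrisk(sprintf(
      "sensor axis near-horizontal (sz <= 0.1) at sample %d", bad[1]))
  }
  out <- tibble(
    time_s = orient$time_s,
    ml_cm = -depth_cm * orient$sx / orient$sz,
    ap_cm = -depth_cm * orient$sy / orient$sz
  )
  class(out) <- c("sway_path", class(out))
  out
}
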