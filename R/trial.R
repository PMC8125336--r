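#' Build an IMU trial table
#'
#' An IMU trial is a tibble with one row per sample: `time_s` (strictly
#' increasing seconds), accelerometer channels `ax, ay, az` (m/s^2, specific
#' force), gyroscope channels `gx, gy, gz` (degrees/s) and optional
#' magnetometer channels `mx, my, mz` (microtesla). Metadata (task, athlete,
#' repetition) travels in attributes so the table stays tidy.
#'
#' @param time_s numeric vector of sample times, strictly increasing.
#' @param accel n x 3 matrix (or data frame) of specific force, m/s^2.
#' @param gyro n x 3 matrix of angular velocity, degrees/s.
#' @param mag optional n x 3 matrix of magnetic field, microtesla.
#' @param task,athlete_id,repetition optional metadata tags.
#' @return a tibble of class `imu_trial`.
#' @export
imu_trial <- function(time_s, accel, gyro, mag = NULL,
                      task = NA_character_, athlete_id = NA_character_,
                      repetition = NA_integer_) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  x <- tibble(
    time_s = as.numeric(time_s),
    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3]
  )
  if (!is.null(mag)) {
    mag <- as.matrix(mag)
    x$mx <- mag[, 1]; x$my <- mag[, 2]; x$mz <- mag[, 3]
  }
  attr(x, "task") <- task
  attr(x, "athlete_id") <- athlete_id
  attr(x, "repetition") <- repetition
  class(x) <- c("imu_trial", class(x))
  validate_imu_trial(x)
}

validate_imu_trial <- function(x) {
  need <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort_swayrisk(paste0("imu_trial is missing columns: ",
                          paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) < 2) abort_swayrisk("an imu_trial needs at least 2 samples")
  dt <- diff(x$time_s)
  if (any(dt <= 0)) abort_swayrisk("imu_trial time must be strictly increasing")
  if (max(dt) > 1.1 * stats::median(dt) + 1e-12 ||
      min(dt) < 0.9 * stats::median(dt) - 1e-12) {
    abort_swayrisk("imu_trial time-step jitter exceeds 10% of nominal")
  }
  x
}

trial_accel <- function(trial) as.matrix(trial[, c("ax", "ay", "az")])
trial_gyro <- function(trial) as.matrix(trial[, c("gx", "gy", "gz")])
trial_rate <- function(trial) 1 / stats::median(diff(trial$time_s))

#' Build an optoelectronic LED status series
#'
#' @param time_s sample times, seconds.
#' @param on logical vector; TRUE while the diodes are interrupted (foot on
#'   the ground), FALSE during flight.
#' @return tibble of class `led_series` with columns `time_s`, `on`.
#' @export
led_series <- function(time_s, on) {
  x <- tibble(time_s = as.numeric(time_s), on = as.logical(on))
  class(x) <- c("led_series", class(x))
  x
}

#' Read / write trial and LED CSV files
#'
#' Trials are stored as tidy CSV with columns
#' `time_s, ax, ay, az, gx, gy, gz[, mx, my, mz]`; LED series as
#' `time_s, on`.
#'
#' @param path file path.
#' @param trial an `imu_trial`.
#' @param led a `led_series`.
#' @return the tibble read, or the input invisibly for writers.
#' @export
read_trial_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  imu_trial(x$time_s, as.matrix(x[, c("ax", "ay", "az")]),
            as.matrix(x[, c("gx", "gy", "gz")]),
            mag = if (all(c("mx", "my", "mz") %in% names(x))) {
              as.matrix(x[, c("mx", "my", "mz")])
            } else NULL)
}

#' @rdname read_trial_csv
#' @export
write_trial_csv <- function(trial, path) {
  readr::write_csv(as_tibble(as.data.frame(trial)), path)
  invisible(trial)
}

#' @rdname read_trial_csv
#' @export
read_led_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  led_series(x$time_s, x$on)
}

#' @rdname read_trial_csv
#' @export
write_led_csv <- function(led, path) {
  readr::write_csv(as_tibble(as.data.frame(led)), path)
  invisible(led)
}
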