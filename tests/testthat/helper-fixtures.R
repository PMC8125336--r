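# shared fixtures, all generated in code

# a sway_path tibble from raw coordinates
make_path <- function(ml, ap, fs = 100) {
  structure(
    tibble::tibble(time_s = (seq_along(ml) - 1) / fs, ml_cm = ml, ap_cm = ap),
    class = c("sway_path", "tbl_df", "tbl", "data.frame")
  )
}

# still trial with exact gravity and no noise
still_trial <- function(duration = 1.5, fs = 100, accel = c(0, 0, 9.81),
                        gyro = c(0, 0, 0)) {
  tt <- seq(0, duration, by = 1 / fs)
  n <- length(tt)
  imu_trial(tt, matrix(rep(accel, each = n), n, 3),
            matrix(rep(gyro, each = n), n, 3))
}

# orientation series for a pure rotation-about-y ramp (degrees)
theta_y_series <- function(theta_deg, fs = 100) {
  n <- length(theta_deg)
  quat <- t(vapply(theta_deg, function(a) {
    r <- a * pi / 180
    c(cos(r / 2), 0, sin(r / 2), 0)
  }, numeric(4)))
  swayrisk:::orientation_series_from_quat((seq_len(n) - 1) / fs, quat)
}

# small two-class feature table with an obvious separator
toy_separable <- function(n_per_class = 20, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    x <- tibble::tibble(
      f1 = c(rnorm(n_per_class, -10, sd), rnorm(n_per_class, 10, sd)),
      f2 = c(rnorm(n_per_class, 10, sd), rnorm(n_per_class, -10, sd))
    )
    list(x = x,
         y = factor(rep(c("NR", "R"), each = n_per_class),
                    levels = c("NR", "R")))
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
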