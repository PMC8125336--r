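test_that("path lengths match hand sums and a brute-force oracle", {
  p <- make_path(c(0, 1, 1, 0), c(0, 0, 1, 1))
  pl <- path_lengths(p)
  expect_equal(pl$pl, 3)
  expect_equal(pl$pl_ml, 2)
  expect_equal(pl$pl_ap, 1)

  # constant path
  p0 <- make_path(rep(0.3, 5), rep(-0.2, 5))
  expect_equal(unlist(path_lengths(p0)), c(pl = 0, pl_ap = 0, pl_ml = 0))

  # random path equals independent per-segment re-summation exactly
  withr::with_seed(42, {
    x <- cumsum(rnorm(1000)); y <- cumsum(rnorm(1000))
  })
  p <- make_path(x, y)
  got <- path_lengths(p)
  pl_oracle <- 0; ap_oracle <- 0; ml_oracle <- 0
  for (i in 2:1000) {
    dx <- x[i] - x[i - 1]; dy <- y[i] - y[i - 1]
    pl_oracle <- pl_oracle + sqrt(dx^2 + dy^2)
    ml_oracle <- ml_oracle + abs(dx)
    ap_oracle <- ap_oracle + abs(dy)
  }
  expect_equal(got$pl, pl_oracle, tolerance = 1e-12)
  expect_equal(got$pl_ml, ml_oracle, tolerance = 1e-12)
  expect_equal(got$pl_ap, ap_oracle, tolerance = 1e-12)

  expect_error(path_lengths(make_path(1, 1)), "at least 2")
})

test_that("path-length triangle inequalities hold on arbitrary inputs", {
  for (s in 1:20) {
    withr::with_seed(s, {
      p <- make_path(cumsum(rnorm(50)), cumsum(rnorm(50)))
    })
    pl <- path_lengths(p)
    expect_gte(pl$pl, max(pl$pl_ap, pl$pl_ml) - 1e-12)
    expect_lte(pl$pl, pl$pl_ap + pl$pl_ml + 1e-12)
  }
})

test_that("ellipse area follows the F-scaled covariance formula", {
  # isotropic uncorrelated cloud: EA = 2*pi*F*s^2 with sample moments
  withr::with_seed(7, {
    x <- rnorm(200, sd = 0.5); y <- rnorm(200, sd = 0.5)
  })
  y <- y - coef(lm(y ~ x))[2] * x # kill sample covariance almost exactly
  p <- make_path(x, y)
  ea <- ellipse_area(p)
  f <- qf(0.99, 2, 198)
  expect_equal(ea, 2 * pi * f * sqrt(var(x) * var(y) - cov(x, y)^2),
               tolerance = 1e-12)

  # translation invariance
  p_shift <- make_path(x + 5, y - 3)
  expect_equal(ellipse_area(p_shift), ea, tolerance = 1e-9)

  # doubling x doubles the area (determinant scaling)
  p2 <- make_path(2 * x, y)
  expect_equal(ellipse_area(p2), 2 * ea, tolerance = 1e-9)

  # isotropic scaling by c scales the area by c^2
  p3 <- make_path(3 * x, 3 * y)
  expect_equal(ellipse_area(p3), 9 * ea, tolerance = 1e-9)
})

test_that("collinear clouds give zero area with a warning", {
  p <- make_path(1:10, 2 * (1:10))
  expect_warning(ea <- ellipse_area(p), "degenerate")
  expect_equal(ea, 0)
})

test_that("the 99% ellipse contains about 99% of Gaussian points", {
  withr::with_seed(12, {
    x <- rnorm(10000); y <- 0.5 * x + rnorm(10000, sd = 0.8)
  })
  p <- make_path(x, y)
  par <- ellipse_params(p)
  si <- solve(par$cov)
  dx <- x - par$center[1]; dy <- y - par$center[2]
  d2 <- si[1, 1] * dx^2 + 2 * si[1, 2] * dx * dy + si[2, 2] * dy^2
  inside <- mean(d2 <= par$r2)
  expect_gte(inside, 0.98)
  # and the quoted area equals pi * product of semiaxes
  ev <- eigen(par$cov, symmetric = TRUE)$values
  expect_equal(par$area, pi * sqrt(par$r2 * ev[1]) * sqrt(par$r2 * ev[2]),
               tolerance = 1e-9)
})

test_that("load-absorption RMS removes gravity and normalizes by Ts", {
  # pure gravity in the absolute frame: both indices are zero
  n <- 101
  tt <- seq(0, 1, by = 0.01)
  tr <- imu_trial(tt, matrix(rep(c(0, 0, 9.81), each = n), n, 3),
                  matrix(0, n, 3))
  o <- mahony_orientation(tr)
  r <- rms_load(tr, o, 0.2, 0.5)
  expect_lt(r$rms_z, 1e-6)
  expect_lt(r$rms_xy, 1e-6)

  # constant vertical surplus of 2 m/s^2 over Ts = 0.5 s: RMS_z = 4
  tr2 <- imu_trial(tt, matrix(rep(c(0, 0, 11.81), each = n), n, 3),
                   matrix(0, n, 3))
  o2 <- mahony_orientation(tr2, accel_gate = 0.1)
  r2 <- rms_load(tr2, o2, 0.2, 0.5)
  expect_equal(r2$rms_z, 4, tolerance = 1e-3)

  expect_error(rms_load(tr2, o2, 5, 0.5), "empty")
})

test_that("stability normalization divides every field by the duration", {
  params <- tibble::tibble(pl = 2, pl_ap = 1, pl_ml = 1.5, ea = 1)
  out <- normalize_stability(params, 2)
  expect_equal(unlist(out), c(pl = 1, pl_ap = 0.5, pl_ml = 0.75, ea = 0.5))
  expect_equal(normalize_stability(params, 1), params)
  expect_error(normalize_stability(params, 0), "positive")
})

test_that("feature vectors average the five repetitions in fixed order", {
  one_m <- tibble::tibble(mcmj_ts = 0.3, mcmj_pl = 2, mcmj_pl_ap = 1,
                          mcmj_pl_ml = 1.5, mcmj_ea = 0.7, mcmj_rms_z = 90,
                          mcmj_rms_xy = 70)
  one_s <- tibble::tibble(sls_t_dp = 3.9, sls_pl = 0.8, sls_pl_ap = 0.6,
                          sls_pl_ml = 0.5, sls_ea = 0.7, sls_theta_ymax = 26)
  five_m <- dplyr::bind_rows(rep(list(one_m), 5))
  five_s <- dplyr::bind_rows(rep(list(one_s), 5))
  fv <- build_feature_vector(five_m, five_s)
  expect_named(fv, acl_feature_names())
  expect_equal(fv$mcmj_pl, 2)

  # mean of {1..5} is 3
  vary <- five_m; vary$mcmj_ts <- 1:5
  fv2 <- build_feature_vector(vary, five_s)
  expect_equal(fv2$mcmj_ts, 3)

  expect_error(build_feature_vector(five_m[0, ], five_s), "zero repetitions")
  expect_error(build_feature_vector(five_m[1:3, ], five_s), "5 repetitions")
  expect_warning(build_feature_vector(five_m[1:3, ], five_s,
                                      allow_fewer = TRUE), "!= 5")
})

test_that("mCMJ features are computed strictly on the landing window", {
  # corrupt the sway signal outside [contact, contact + Ts]: features must
  # not change
  rec <- recipe_from_group("mCMJ", "NR", 0, seed = 21)
  out <- synthesize_jump_trial(rec)
  f0 <- extract_jump_features(out$trial, out$led, out$static)
  tc <- detect_contact(out$led)
  ts <- f0$mcmj_ts
  tampered <- out$trial
  # leave a guard band beyond the window: the zero-phase smoother used by
  # the Ts search is non-causal over ~0.2 s
  late <- tampered$time_s > tc + ts + 0.35
  tampered$gx[late] <- tampered$gx[late] + 25
  f1 <- extract_jump_features(tampered, out$led, out$static)
  expect_equal(f1$mcmj_pl, f0$mcmj_pl, tolerance = 1e-6)
  expect_equal(f1$mcmj_ea, f0$mcmj_ea, tolerance = 1e-6)
  expect_equal(f1$mcmj_rms_z, f0$mcmj_rms_z, tolerance = 1e-6)
})
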