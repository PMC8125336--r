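test_that("path-target reconciliation projects into the feasible interval", {
  # any planar path: sqrt(AP^2 + ML^2) <= PL <= AP + ML
  expect_error(sway_recipe("mCMJ", list(ts = 0.3, pl = 1, pl_ap = 3,
                                        pl_ml = 3, ea = 0.5, rms_z = 90,
                                        rms_xy = 70)),
               class = "swayrisk_infeasible_error")
  expect_error(sway_recipe("mCMJ", list(ts = 0.3, pl = 10, pl_ap = 3,
                                        pl_ml = 3, ea = 0.5, rms_z = 90,
                                        rms_xy = 70)),
               class = "swayrisk_infeasible_error")
  pl <- reconcile_path_targets(1, 3, 3)
  expect_gte(pl, sqrt(18))
  pl2 <- reconcile_path_targets(10, 3, 3)
  expect_lte(pl2, 6)
  # an interior value is untouched
  expect_equal(reconcile_path_targets(5.2, 3, 3), 5.2)
})

test_that("recipe validation enforces positive times and rates", {
  tg <- list(ts = -1, pl = 1, pl_ap = 0.5, pl_ml = 0.7, ea = 0.2,
             rms_z = 9, rms_xy = 7)
  expect_error(sway_recipe("mCMJ", tg), "positive")
  tg$ts <- 0.3
  expect_error(sway_recipe("mCMJ", tg, sample_rate = 0), "sample_rate")
  tg$ea <- -1
  expect_error(sway_recipe("mCMJ", tg), "EA")
  expect_error(sway_recipe("mCMJ", tg[-2]), "missing targets")
})

test_that("jump trials realize their targets through full extraction", {
  for (case in list(c("NR", 0), c("NR", 1), c("R", 0), c("R", -1))) {
    rec <- recipe_from_group("mCMJ", case[1], as.numeric(case[2]), seed = 3)
    out <- synthesize_jump_trial(rec)
    f <- extract_jump_features(out$trial, out$led, out$static)
    rel <- as.numeric(f) / as.numeric(out$targets) - 1
    expect_lt(max(abs(rel)), 0.10,
              label = paste("max relative error,", case[1], case[2]))
  }
})

test_that("squat trials realize their targets through full extraction", {
  for (case in list(c("NR", 0), c("NR", -1), c("R", 0), c("R", 1))) {
    rec <- recipe_from_group("SLS", case[1], as.numeric(case[2]), seed = 4)
    out <- synthesize_squat_trial(rec)
    f <- extract_squat_features(out$trial, out$static)
    rel <- as.numeric(f) / as.numeric(out$targets) - 1
    expect_lt(max(abs(rel)), 0.10,
              label = paste("max relative error,", case[1], case[2]))
  }
})

test_that("theta_ymax and T_DP are recovered at the published group values", {
  for (case in list(list("R", 16.8, 3.22), list("NR", 26.0, 3.90))) {
    rec <- recipe_from_group("SLS", case[[1]], 0, seed = 8)
    expect_equal(rec$targets$theta_ymax, case[[2]])
    expect_equal(rec$targets$t_dp, case[[3]])
    out <- synthesize_squat_trial(rec)
    f <- extract_squat_features(out$trial, out$static)
    expect_lt(abs(f$sls_theta_ymax - case[[2]]), 0.5)
    expect_lt(abs(f$sls_t_dp - case[[3]]), 0.05)
  }
})

test_that("a zero-amplitude jump recipe extracts all-zero sway", {
  rec <- sway_recipe("mCMJ", list(ts = 0.3, pl = 0, pl_ap = 0, pl_ml = 0,
                                  ea = 0, rms_z = 0, rms_xy = 0),
                     seed = 5, noise_gyro_dps = 0, noise_accel = 0)
  out <- synthesize_jump_trial(rec)
  suppressWarnings(f <- extract_jump_features(out$trial, out$led, out$static))
  expect_lt(f$mcmj_pl, 1e-6)
  expect_lt(f$mcmj_pl_ap, 1e-6)
  expect_lt(f$mcmj_pl_ml, 1e-6)
  expect_equal(f$mcmj_ea, 0)
  expect_lt(f$mcmj_rms_z, 0.05)
  # the stabilization time stays detectable from the heading envelope
  expect_equal(f$mcmj_ts, 0.3, tolerance = 0.04)
})

test_that("synthesis is bit-identical under a fixed seed", {
  rec <- recipe_from_group("mCMJ", "R", 0, seed = 17)
  a <- synthesize_jump_trial(rec)
  b <- synthesize_jump_trial(rec)
  expect_identical(a$trial, b$trial)
  expect_identical(a$led, b$led)
  rec2 <- recipe_from_group("SLS", "R", 0, seed = 17)
  s1 <- synthesize_squat_trial(rec2)
  s2 <- synthesize_squat_trial(rec2)
  expect_identical(s1$trial, s2$trial)
})

test_that("trial and LED series round-trip through CSV", {
  rec <- recipe_from_group("mCMJ", "NR", 0, seed = 31)
  out <- synthesize_jump_trial(rec)
  tdir <- withr::local_tempdir()
  write_trial_csv(out$trial, file.path(tdir, "trial.csv"))
  write_led_csv(out$led, file.path(tdir, "led.csv"))
  tr <- read_trial_csv(file.path(tdir, "trial.csv"))
  led <- read_led_csv(file.path(tdir, "led.csv"))
  expect_equal(as.data.frame(tr), as.data.frame(out$trial), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(led$on, out$led$on)
  # extraction from the round-tripped files matches
  f1 <- extract_jump_features(out$trial, out$led, out$static)
  f2 <- extract_jump_features(tr, led, out$static)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-6)
})

test_that("static trials pass the stillness gate and carry the mount tilt", {
  st <- synthesize_static_trial(mount_tilt_deg = 5, seed = 2)
  C <- estimate_static_alignment(st)
  v <- unclass(C) %*% colMeans(swayrisk:::trial_accel(st))
  expect_lt(max(abs(v[1:2])), 1e-6 * 9.81)
  ang <- acos(min(1, v[3] / sqrt(sum(v^2)))) # should be ~0 after correction
  expect_lt(ang, 1e-6)
})
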