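# ---- signal-level synthetic trials ------------------------------------------
#
# The signal model is additive-piecewise: quiet stance, flight (LED off,
# near-zero specific force), a landing window in which the projected vertical
# axis traces a designed sway shape while a high-frequency zero-mean impact
# burst rides on the specific force, and a post-window recovery. No
# biomechanical dynamics are simulated; the point of the generator is that
# the features extracted by the package equal known ground truth.

#' Reconcile path-length targets
#'
#' Any planar path satisfies
#' `sqrt(PL_AP^2 + PL_ML^2) <= PL <= PL_AP + PL_ML`, so a requested total
#' path length outside that interval cannot be realized by any signal; this
#' helper projects `pl` into the feasible interval (with a small interior
#' margin that keeps the shape designer away from the degenerate extremes).
#' Published group-mean path lengths violate the interval on the jump task,
#' hence recipes built from them must be reconciled first.
#'
#' @param pl,pl_ap,pl_ml path-length targets (same units).
#' @param margin interior margin as a fraction of the interval end points.
#' @return the reconciled `pl`.
#' @export
reconcile_path_targets <- function(pl, pl_ap, pl_ml, margin = 0.12) {
  lo <- sqrt(pl_ap^2 + pl_ml^2) * (1 + margin)
  hi <- (pl_ap + pl_ml) * (1 - margin / 2)
  min(max(pl, lo), hi)
}

check_path_targets <- function(pl, pl_ap, pl_ml) {
  if (any(c(pl, pl_ap, pl_ml) < 0)) abort_swayrisk("path lengths must be >= 0")
  if (pl < sqrt(pl_ap^2 + pl_ml^2) - 1e-9) {
    abort_swayrisk(
      "infeasible target PL: below sqrt(PL_AP^2 + PL_ML^2); see reconcile_path_targets()",
      class = "swayrisk_infeasible_error")
  }
  if (pl > pl_ap + pl_ml + 1e-9) {
    abort_swayrisk(
      "infeasible target PL: above PL_AP + PL_ML; see reconcile_path_targets()",
      class = "swayrisk_infeasible_error")
  }
  invisible(TRUE)
}

#' Build a signal recipe
#'
#' A recipe carries the ground-truth feature values a synthesized trial must
#' realize, on the time-normalized reporting scale (per second of Ts or
#' T_DP).
#'
#' @param task `"mCMJ"` or `"SLS"`.
#' @param targets named list / vector of target features. For `mCMJ`:
#'   `ts, pl, pl_ap, pl_ml, ea, rms_z, rms_xy`; for `SLS`:
#'   `t_dp, pl, pl_ap, pl_ml, ea, theta_ymax`.
#' @param sample_rate sampling rate, Hz.
#' @param seed integer seed for the trial noise.
#' @param t_contact ground-contact time for the jump task, s.
#' @param level ellipse coverage level assumed for the EA target.
#' @param mount_tilt_deg fixed sensor mounting tilt about the x axis,
#'   corrected downstream by the static re-alignment.
#' @param noise_gyro_dps,noise_accel gyro / accelerometer noise SD.
#' @return list of class `sway_recipe`.
#' @export
sway_recipe <- function(task = c("mCMJ", "SLS"), targets, sample_rate = 100,
                        seed = 1, t_contact = 1.25, level = 0.99,
                        mount_tilt_deg = 2, noise_gyro_dps = 0.2,
                        noise_accel = 0.03) {
  task <- match.arg(task)
  targets <- as.list(targets)
  need <- if (task == "mCMJ") {
    c("ts", "pl", "pl_ap", "pl_ml", "ea", "rms_z", "rms_xy")
  } else {
    c("t_dp", "pl", "pl_ap", "pl_ml", "ea", "theta_ymax")
  }
  missing_t <- setdiff(need, names(targets))
  if (length(missing_t) > 0) {
    abort_swayrisk(paste0("recipe is missing targets: ",
                          paste(missing_t, collapse = ", ")))
  }
  tkey <- if (task == "mCMJ") "ts" else "t_dp"
  if (targets[[tkey]] <= 0) abort_swayrisk("time targets must be positive")
  if (targets$ea < 0) abort_swayrisk("EA target must be nonnegative")
  if (sample_rate <= 0) abort_swayrisk("sample_rate must be positive")
  dur <- targets[[tkey]]
  if (targets$pl > 0) {
    check_path_targets(targets$pl * dur, targets$pl_ap * dur,
                       targets$pl_ml * dur)
  }
  structure(list(task = task, targets = targets, sample_rate = sample_rate,
                 seed = seed, t_contact = t_contact, level = level,
                 mount_tilt_deg = mount_tilt_deg,
                 noise_gyro_dps = noise_gyro_dps, noise_accel = noise_accel),
            class = "sway_recipe")
}

#' Recipes parameterized from the published group models
#'
#' Builds a [sway_recipe()] at a group's feature means shifted by
#' `shift_sd` standard deviations, with the total path length reconciled
#' into the feasible interval.
#'
#' @param task `"mCMJ"` or `"SLS"`.
#' @param group `"NR"` or `"R"`.
#' @param shift_sd shift applied to every feature, in group SDs.
#' @param ... forwarded to [sway_recipe()].
#' @return a `sway_recipe`.
#' @export
recipe_from_group <- function(task = c("mCMJ", "SLS"),
                              group = c("NR", "R"), shift_sd = 0, ...) {
  task <- match.arg(task); group <- match.arg(group)
  tab <- acl_group_models()
  mu <- if (group == "R") tab$r_mean else tab$nr_mean
  s <- if (group == "R") tab$r_sd else tab$nr_sd
  v <- stats::setNames(mu + shift_sd * s, tab$feature)
  v <- pmax(v, 0.01)
  if (task == "mCMJ") {
    dur <- v[["mcmj_ts"]]
    pl <- reconcile_path_targets(v[["mcmj_pl"]] * dur,
                                 v[["mcmj_pl_ap"]] * dur,
                                 v[["mcmj_pl_ml"]] * dur) / dur
    sway_recipe("mCMJ", list(
      ts = v[["mcmj_ts"]], pl = pl, pl_ap = v[["mcmj_pl_ap"]],
      pl_ml = v[["mcmj_pl_ml"]], ea = v[["mcmj_ea"]],
      rms_z = v[["mcmj_rms_z"]], rms_xy = v[["mcmj_rms_xy"]]), ...)
  } else {
    dur <- v[["sls_t_dp"]]
    pl <- reconcile_path_targets(v[["sls_pl"]] * dur,
                                 v[["sls_pl_ap"]] * dur,
                                 v[["sls_pl_ml"]] * dur) / dur
    # the ellipse area a squat window can support is bounded by the sway
    # the path budgets allow; probe the designer at maximal amplitude and
    # clamp (the published SLS ellipse areas carry a 0.0 SD, so shifted
    # recipes would otherwise demand more spread than the shrunken budgets
    # can realize)
    n_ramp <- round(dur * 100) + 1
    probe <- design_squat_osc(n_ramp, v[["sls_theta_ymax"]],
                              v[["sls_pl_ml"]] * dur, v[["sls_pl_ap"]] * dur,
                              1e9, level = 0.99)
    ea <- min(v[["sls_ea"]], 0.6 * probe$measured$ea / dur)
    sway_recipe("SLS", list(
      t_dp = v[["sls_t_dp"]], pl = pl, pl_ap = v[["sls_pl_ap"]],
      pl_ml = v[["sls_pl_ml"]], ea = ea,
      theta_ymax = v[["sls_theta_ymax"]]), ...)
  }
}

# ---- sway-shape design -------------------------------------------------------

# blended Lissajous shape at unit amplitudes: lambda = 0 gives an ellipse
# (minimal path per cycle), lambda = 1 a rounded square tour whose
# transitions are axis-aligned (maximal path) and whose corner dwells
# maximize the spread per unit of travelled path
lissajous_blend <- function(phase, lambda, kappa = 5) {
  cx <- cos(phase); sy <- sin(phase)
  sqx <- tanh(kappa * cx) / tanh(kappa)
  sqy <- tanh(kappa * sy) / tanh(kappa)
  cbind((1 - lambda) * cx + lambda * sqx,
        (1 - lambda) * sy + lambda * sqy)
}

# place n samples along the (a, b)-scaled blend shape at cumulative arc
# positions proportional to the n-1 speed weights w
sample_shape_by_arc <- function(a, b, n_cyc, lambda, n, w) {
  m <- max(600, ceiling(n_cyc * 128))
  ph <- seq(0, 2 * pi * n_cyc, length.out = m)
  S <- lissajous_blend(ph, lambda)
  S[, 1] <- a * S[, 1]; S[, 2] <- b * S[, 2]
  arc <- c(0, cumsum(sqrt(diff(S[, 1])^2 + diff(S[, 2])^2)))
  pos <- c(0, cumsum(w)) / sum(w) * arc[m]
  cbind(stats::approx(arc, S[, 1], xout = pos, ties = "ordered")$y,
        stats::approx(arc, S[, 2], xout = pos, ties = "ordered")$y)
}

measure_path_matrix <- function(P, level) {
  n <- nrow(P)
  dx <- diff(P[, 1]); dy <- diff(P[, 2])
  det <- stats::var(P[, 1]) * stats::var(P[, 2]) -
    stats::cov(P[, 1], P[, 2])^2
  list(pl = sum(sqrt(dx^2 + dy^2)), ap = sum(abs(dy)), ml = sum(abs(dx)),
       ea = 2 * pi * stats::qf(level, 2, n - 2) * sqrt(max(det, 0)))
}

# design an n-point sway path with prescribed raw path lengths and ellipse
# area; w gives the n-1 relative speeds along the path
design_jump_path <- function(n, l_ml, l_ap, l_pl, a_e, level, w,
                             tol = 0.01, max_iter = 40) {
  if (l_pl <= 1e-12) return(matrix(0, n, 2))
  if (l_ml <= 1e-12 || l_ap <= 1e-12) {
    # degenerate one-axis sway: straight zigzag
    ax <- if (l_ml > 0) 1 else 2
    tot <- max(l_ml, l_ap)
    P <- matrix(0, n, 2)
    amp <- tot / 4
    pos <- c(0, cumsum(w)) / sum(w) * tot
    P[, ax] <- amp * (abs(((pos / amp) + 1) %% 4 - 2) - 1)
    return(P)
  }
  # one candidate path for a given blend and cycle count: budget-scaled
  # shape with the ML/AP totals fixed exactly by a diagonal rescale
  build_candidate <- function(lambda, n_cyc) {
    Q <- sample_shape_by_arc(l_ml / (4 * n_cyc), l_ap / (4 * n_cyc),
                             n_cyc, lambda, n, w)
    mq <- measure_path_matrix(Q, level)
    if (mq$ml > 0) Q[, 1] <- Q[, 1] * l_ml / mq$ml
    if (mq$ap > 0) Q[, 2] <- Q[, 2] * l_ap / mq$ap
    Q
  }
  nc_lo <- 0.625; nc_hi <- max(n / 8, 1)
  best_P <- NULL; best_err <- Inf
  for (lambda in c(0, 0.25, 0.5, 0.75, 1)) {
    # EA decreases smoothly with the cycle count at fixed budgets
    # (amplitude ~ budget / cycles): bisect, then keep whichever candidate
    # best trades the EA and PL errors
    lo <- nc_lo; hi <- nc_hi
    ea_lo <- measure_path_matrix(build_candidate(lambda, lo), level)$ea
    ea_hi <- measure_path_matrix(build_candidate(lambda, hi), level)$ea
    if (a_e > 0 && ea_lo < a_e) {
      nc_star <- lo # amplitude-starved: best effort at the boundary
    } else if (a_e > 0 && ea_hi > a_e) {
      nc_star <- hi
    } else if (a_e > 0) {
      for (it in seq_len(18)) {
        mid <- (lo + hi) / 2
        if (measure_path_matrix(build_candidate(lambda, mid), level)$ea > a_e) {
          lo <- mid
        } else {
          hi <- mid
        }
      }
      nc_star <- (lo + hi) / 2
    } else {
      nc_star <- 1
    }
    for (nc in unique(pmin(pmax(nc_star * c(0.96, 1, 1.04), nc_lo), nc_hi))) {
      Q <- build_candidate(lambda, nc)
      mq <- measure_path_matrix(Q, level)
      worst <- max(abs((if (a_e > 0) mq$ea / a_e else 1) - 1),
                   abs(mq$pl / l_pl - 1))
      if (worst < best_err) { best_err <- worst; best_P <- Q }
    }
  }
  P <- best_P
  m <- measure_path_matrix(P, level)
  if (a_e > 0 && abs(m$ea / a_e - 1) > 0.10) {
    abort_swayrisk(sprintf(
      "infeasible target EA: designed %.3g vs requested %.3g (path budget too small)",
      m$ea, a_e), class = "swayrisk_infeasible_error")
  }
  if (abs(m$pl / l_pl - 1) > 0.12) {
    abort_swayrisk(sprintf(
      "infeasible target PL: designed %.3g vs requested %.3g",
      m$pl, l_pl), class = "swayrisk_infeasible_error")
  }
  P
}

# ---- path -> trial -----------------------------------------------------------

# quaternions realizing a projected sway path: S ~ (-ml, -ap, depth); an
# optional heading angle (rad) spins the sensor about its vertical axis,
# which leaves S and hence the sway projection unchanged
quats_from_path <- function(P, depth_cm = 1.0, q_mount = c(1, 0, 0, 0),
                            yaw = NULL) {
  n <- nrow(P)
  Q <- matrix(0, n, 4)
  for (k in seq_len(n)) {
    s <- c(-P[k, 1], -P[k, 2], depth_cm)
    q <- quat_between(c(0, 0, 1), s / sqrt(sum(s^2)))
    if (!is.null(yaw) && yaw[k] != 0) {
      qy <- c(cos(yaw[k] / 2), 0, 0, sin(yaw[k] / 2))
      q <- quat_multiply(q, qy)
    }
    Q[k, ] <- quat_multiply(q, q_mount)
  }
  Q
}

# body-frame gyro (deg/s) realizing a quaternion sequence
gyro_from_quats <- function(Q, dt) {
  n <- nrow(Q)
  G <- matrix(0, n, 3)
  for (k in 2:n) {
    dq <- quat_multiply(quat_conjugate(Q[k - 1, ]), Q[k, ])
    G[k, ] <- quat_to_rotvec(dq) / dt * 180 / pi
  }
  G
}

# body-frame specific force for a quasi-static rotation sequence plus a
# world-frame additive burst; `grounded` marks samples with ground support
accel_from_quats <- function(Q, burst_world, grounded) {
  n <- nrow(Q)
  A <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    if (grounded[k]) {
      aw <- c(burst_world[k, 1], burst_world[k, 2], GRAVITY + burst_world[k, 3])
      A[k, ] <- t(quat_to_matrix(Q[k, ])) %*% aw
    }
  }
  A
}

#' Synthesize a static upright calibration trial
#'
#' @param duration_s trial length, s.
#' @param sample_rate Hz.
#' @param mount_tilt_deg fixed sensor tilt about x, degrees.
#' @param noise_gyro_dps,noise_accel sensor noise SDs.
#' @param seed integer seed.
#' @return an [imu_trial()].
#' @export
synthesize_static_trial <- function(duration_s = 1.5, sample_rate = 100,
                                    mount_tilt_deg = 2, noise_gyro_dps = 0.2,
                                    noise_accel = 0.03, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tt <- seq(0, duration_s, by = 1 / sample_rate)
  n <- length(tt)
  Rm <- rotation_about("x", mount_tilt_deg)
  a0 <- as.numeric(t(Rm) %*% c(0, 0, GRAVITY))
  accel <- matrix(rep(a0, each = n), n, 3) +
    matrix(stats::rnorm(3 * n, 0, noise_accel), n, 3)
  gyro <- matrix(stats::rnorm(3 * n, 0, noise_gyro_dps), n, 3)
  mag <- matrix(rep(as.numeric(t(Rm) %*% c(20, 0, 43)), each = n), n, 3) +
    matrix(stats::rnorm(3 * n, 0, 0.3), n, 3)
  imu_trial(tt, accel, gyro, mag, task = "static")
}

mount_quat <- function(mount_tilt_deg) {
  a <- mount_tilt_deg * pi / 180
  c(cos(a / 2), sin(a / 2), 0, 0)
}

# speed weights over the landing window: brief ramp-in, then a strict decay
# whose minimum falls exactly on the last window sample, so the first local
# minimum of |omega| after contact marks Ts
jump_speed_weights <- function(n_win, fs, ts) {
  u <- (seq_len(n_win - 1) - 0.5) / fs
  w <- 0.25 + ((ts - u) / ts)^1.8
  ramp <- pmin(1, u / 0.03)
  w * ramp
}

build_jump_signals <- function(recipe, ts_design, l_budget, burst_scale) {
  fs <- recipe$sample_rate
  dt <- 1 / fs
  t_c <- recipe$t_contact
  t_flight <- 0.40
  t_post <- 0.45
  t_end <- t_c + ts_design + t_post + 0.4
  tt <- seq(0, t_end, by = dt)
  n <- length(tt)
  i_to <- which.min(abs(tt - (t_c - t_flight)))
  i_c <- which.min(abs(tt - t_c))
  i_ts <- which.min(abs(tt - (t_c + ts_design)))
  n_win <- i_ts - i_c + 1

  w <- jump_speed_weights(n_win, fs, ts_design)
  P_win <- design_jump_path(n_win, l_budget[["ml"]], l_budget[["ap"]],
                            l_budget[["pl"]], l_budget[["ea"]],
                            recipe$level, w)
  # translate so the window starts at the stance origin
  P_win[, 1] <- P_win[, 1] - P_win[1, 1]
  P_win[, 2] <- P_win[, 2] - P_win[1, 2]

  # post-window recovery: speed rises off the Ts minimum then dies out
  n_post <- round(t_post * fs)
  v_min <- sqrt(sum((P_win[n_win, ] - P_win[n_win - 1, ])^2))
  p_end <- P_win[n_win, ]
  dirv <- if (sqrt(sum(p_end^2)) > 1e-9) -p_end / sqrt(sum(p_end^2)) else c(1, 0)
  inc <- v_min * (1 + 3 * sin(pi * seq_len(n_post) / n_post)) *
    (1 - seq_len(n_post) / n_post * 0.8)
  P_post <- cbind(p_end[1] + dirv[1] * cumsum(inc),
                  p_end[2] + dirv[2] * cumsum(inc))

  P <- matrix(0, n, 2)
  P[i_c:i_ts, ] <- P_win
  P[(i_ts + 1):(i_ts + n_post), ] <- P_post
  if (i_ts + n_post < n) {
    P[(i_ts + n_post + 1):n, 1] <- P_post[n_post, 1]
    P[(i_ts + n_post + 1):n, 2] <- P_post[n_post, 2]
  }

  # heading (yaw) component about the sensor's own vertical axis: it leaves
  # the sway projection untouched but gives |omega| the same rise-and-decay
  # envelope as the sway speed, so the Ts minimum survives even for
  # zero-sway recipes
  yaw_rate <- rep(0, n) # rad/s
  # a chord of x cm on the 1-cm projection plane is ~x rad of tilt
  tilt_rate_peak <- max(sqrt(rowSums(diff(P_win)^2))) / dt
  yaw_scale <- max(0.5, 0.6 * tilt_rate_peak)
  yaw_rate[(i_c + 1):i_ts] <- yaw_scale * w / max(w)
  yaw_rate[(i_ts + 1):(i_ts + n_post)] <-
    yaw_scale * min(w) / max(w) * (1 + 3 * sin(pi * seq_len(n_post) / n_post)) *
    (1 - seq_len(n_post) / n_post)
  yaw <- cumsum(yaw_rate) * dt

  qm <- mount_quat(recipe$mount_tilt_deg)
  Q <- quats_from_path(P, 1.0, qm, yaw = yaw)
  G <- gyro_from_quats(Q, dt)

  # zero-mean high-frequency impact burst in the absolute frame over the
  # landing window; scaled so the extracted RMS indices hit their targets
  burst <- matrix(0, n, 3)
  u <- tt[i_c:i_ts] - t_c
  env <- exp(-u / (0.5 * ts_design))
  bz <- sin(2 * pi * 22 * u + 0.3) * env
  bx <- sin(2 * pi * 18 * u) * env
  by <- 0.6 * sin(2 * pi * 14 * u + 1.0) * env
  rms <- function(x) sqrt(mean(x^2))
  sz <- burst_scale[["z"]] / max(rms(bz), 1e-12)
  sxy <- burst_scale[["xy"]] / max(rms(sqrt(bx^2 + by^2)), 1e-12)
  burst[i_c:i_ts, 1] <- sxy * bx
  burst[i_c:i_ts, 2] <- sxy * by
  burst[i_c:i_ts, 3] <- sz * bz

  grounded <- rep(TRUE, n)
  grounded[(i_to + 1):(i_c - 1)] <- FALSE
  A <- accel_from_quats(Q, burst, grounded)

  A <- A + matrix(stats::rnorm(3 * n, 0, recipe$noise_accel), n, 3)
  G <- G + matrix(stats::rnorm(3 * n, 0, recipe$noise_gyro_dps), n, 3)
  Rm <- quat_to_matrix(qm)
  mag <- matrix(rep(as.numeric(t(Rm) %*% c(20, 0, 43)), each = n), n, 3) +
    matrix(stats::rnorm(3 * n, 0, 0.3), n, 3)

  trial <- imu_trial(tt, A, G, mag, task = "mCMJ")
  led <- led_series(tt, grounded)
  list(trial = trial, led = led)
}

#' Synthesize a single-jump landing trial with known ground truth
#'
#' Produces one monopodalic countermovement-jump repetition (stance, flight
#' with the optoelectronic LEDs uninterrupted, landing, recovery) whose
#' extracted features match the recipe targets. The generator iteratively
#' calibrates its sway-shape and burst amplitudes against the package's own
#' extraction chain, so the returned `targets` are realized by construction
#' up to sensor noise.
#'
#' @param recipe a [sway_recipe()] with task `"mCMJ"`.
#' @return list with `trial` (the [imu_trial()]), `led` (the
#'   [led_series()]), `static` (a matching calibration trial) and `targets`
#'   (the ground-truth feature tibble on the normalized scale).
#' @export
synthesize_jump_trial <- function(recipe) {
  stopifnot(inherits(recipe, "sway_recipe"), recipe$task == "mCMJ")
  tg <- recipe$targets
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(recipe$seed)

  static <- synthesize_static_trial(
    1.5, recipe$sample_rate, recipe$mount_tilt_deg,
    recipe$noise_gyro_dps, recipe$noise_accel,
    seed = recipe$seed + 1000003L)

  ts_design <- tg$ts
  l_budget <- c(ml = tg$pl_ml * tg$ts, ap = tg$pl_ap * tg$ts,
                pl = tg$pl * tg$ts, ea = tg$ea * tg$ts)
  burst_scale <- c(z = tg$rms_z * tg$ts, xy = tg$rms_xy * tg$ts)

  out <- NULL
  for (it in 1:5) {
    out <- build_jump_signals(recipe, ts_design, l_budget, burst_scale)
    feats <- extract_jump_features(out$trial, out$led, static,
                                   level = recipe$level)
    rel <- function(x, t) if (abs(t) > 1e-12) x / t else 1
    errs <- c(
      ts = feats$mcmj_ts - tg$ts,
      pl = rel(feats$mcmj_pl, tg$pl), ap = rel(feats$mcmj_pl_ap, tg$pl_ap),
      ml = rel(feats$mcmj_pl_ml, tg$pl_ml), ea = rel(feats$mcmj_ea, tg$ea),
      z = rel(feats$mcmj_rms_z, tg$rms_z),
      xy = rel(feats$mcmj_rms_xy, tg$rms_xy)
    )
    ok <- abs(errs[["ts"]]) < 0.6 / recipe$sample_rate &&
      all(abs(errs[c("pl", "ap", "ml", "ea", "z", "xy")] - 1) < 0.02)
    if (ok) break
    ts_design <- ts_design - errs[["ts"]]
    adj <- function(x, e) x / min(max(e, 0.5), 2)
    l_budget[["ml"]] <- adj(l_budget[["ml"]], errs[["ml"]])
    l_budget[["ap"]] <- adj(l_budget[["ap"]], errs[["ap"]])
    l_budget[["pl"]] <- reconcile_path_targets(
      adj(l_budget[["pl"]], errs[["pl"]]),
      l_budget[["ap"]], l_budget[["ml"]], margin = 0.10)
    l_budget[["ea"]] <- adj(l_budget[["ea"]], errs[["ea"]])
    burst_scale[["z"]] <- adj(burst_scale[["z"]], errs[["z"]])
    burst_scale[["xy"]] <- adj(burst_scale[["xy"]], errs[["xy"]])
  }
  list(trial = out$trial, led = out$led, static = static,
       targets = tibble(
         mcmj_ts = tg$ts, mcmj_pl = tg$pl, mcmj_pl_ap = tg$pl_ap,
         mcmj_pl_ml = tg$pl_ml, mcmj_ea = tg$ea,
         mcmj_rms_z = tg$rms_z, mcmj_rms_xy = tg$rms_xy))
}

# squat sway: monotone knee-flexion ramp in the ML projection plus
# downward-only dips (which never raise theta_y above the apex) and an
# orthogonal AP oscillation
build_squat_path <- function(n, theta_max_deg, dip_amp, ap_amp, n_cyc,
                             lambda = 0) {
  u <- seq(0, 1, length.out = n)
  m_apex <- tan(theta_max_deg * pi / 180)
  base <- m_apex * (1 - (1 - u)^1.5)
  # taper the oscillation at both window ends so the apex stays the strict
  # theta_y maximum for any (non-integer) cycle count
  taper <- pmin(1, u / 0.03) * pmin(1, (1 - u) / 0.12)
  dip <- dip_amp * (1 - cos(2 * pi * n_cyc * u)) / 2 * taper
  # lambda squares up the AP waveform: AP then moves while the dip is
  # parked, which lengthens the total path at fixed axis budgets
  s <- sin(2 * pi * n_cyc * u)
  ap_wave <- (1 - lambda) * s + lambda * tanh(5 * s) / tanh(5)
  ap <- ap_amp * ap_wave * taper
  cbind(-(base - dip), ap)
}

# choose squat oscillation parameters so the ramp-window geometry hits the
# raw path-length and ellipse-area targets: amplitudes by fixed point
# (ML/AP totals are monotone in them), cycle count by bisection on EA
design_squat_osc <- function(n, theta_max_deg, l_ml, l_ap, a_e, level,
                             l_pl = NULL, lambda_fixed = NULL) {
  fit_amps <- function(n_cyc, lambda) {
    dip <- max((l_ml - tan(theta_max_deg * pi / 180)) / (2 * n_cyc), 1e-4)
    ap <- max(l_ap / (4 * n_cyc), 1e-4)
    m <- NULL
    for (it in 1:10) {
      P <- build_squat_path(n, theta_max_deg, dip, ap, n_cyc, lambda)
      m <- measure_path_matrix(P, level)
      r_ml <- l_ml / m$ml; r_ap <- l_ap / m$ap
      if (abs(r_ml - 1) < 0.005 && abs(r_ap - 1) < 0.005) break
      base_tv <- tan(theta_max_deg * pi / 180)
      dip <- dip * max((l_ml - base_tv), 1e-4) /
        max(m$ml - base_tv, 1e-4)
      ap <- ap * r_ap
    }
    list(dip = dip, ap = ap, m = m)
  }
  best <- NULL; best_err <- Inf
  lambdas <- if (is.null(lambda_fixed)) c(0, 0.5, 1) else lambda_fixed
  for (lambda in lambdas) {
    lo <- 1; hi <- max(n / 10, 2)
    if (fit_amps(lo, lambda)$m$ea < a_e) {
      nc <- lo
    } else if (fit_amps(hi, lambda)$m$ea > a_e) {
      nc <- hi
    } else {
      for (it in 1:16) {
        mid <- (lo + hi) / 2
        if (fit_amps(mid, lambda)$m$ea > a_e) lo <- mid else hi <- mid
      }
      nc <- (lo + hi) / 2
    }
    out <- fit_amps(nc, lambda)
    err <- abs(out$m$ea / max(a_e, 1e-12) - 1)
    if (!is.null(l_pl)) err <- max(err, 0.5 * abs(out$m$pl / l_pl - 1))
    if (err < best_err) {
      best_err <- err
      best <- list(dip_amp = out$dip, ap_amp = out$ap, n_cyc = nc,
                   lambda = lambda, measured = out$m)
    }
  }
  best
}

build_squat_signals <- function(recipe, t_ramp, theta_max_deg, dip_amp,
                                ap_amp, n_cyc, lambda = 0) {
  fs <- recipe$sample_rate
  dt <- 1 / fs
  t_hold <- 2.0
  t_asc <- 0.7 * t_ramp
  t_end <- t_hold + t_ramp + t_asc + 1.0
  tt <- seq(0, t_end, by = dt)
  n <- length(tt)
  i0 <- which.min(abs(tt - t_hold))
  i1 <- which.min(abs(tt - (t_hold + t_ramp)))
  n_ramp <- i1 - i0 + 1

  P <- matrix(0, n, 2)
  P[i0:i1, ] <- build_squat_path(n_ramp, theta_max_deg, dip_amp,
                                 ap_amp, n_cyc, lambda)
  # ascent back toward upright, strictly below the apex
  m_apex <- tan(theta_max_deg * pi / 180)
  i2 <- which.min(abs(tt - (t_hold + t_ramp + t_asc)))
  if (i2 > i1) {
    v <- (tt[(i1 + 1):i2] - tt[i1]) / t_asc
    P[(i1 + 1):i2, 1] <- -m_apex * (1 - pmin(v, 1)^1.5)
  }

  qm <- mount_quat(recipe$mount_tilt_deg)
  Q <- quats_from_path(P, 1.0, qm)
  G <- gyro_from_quats(Q, dt)
  A <- accel_from_quats(Q, matrix(0, n, 3), rep(TRUE, n))
  A <- A + matrix(stats::rnorm(3 * n, 0, recipe$noise_accel), n, 3)
  G <- G + matrix(stats::rnorm(3 * n, 0, recipe$noise_gyro_dps), n, 3)
  Rm <- quat_to_matrix(qm)
  mag <- matrix(rep(as.numeric(t(Rm) %*% c(20, 0, 43)), each = n), n, 3) +
    matrix(stats::rnorm(3 * n, 0, 0.3), n, 3)
  imu_trial(tt, A, G, mag, task = "SLS")
}

#' Synthesize a single-leg-squat trial with known ground truth
#'
#' Static hold, a smooth monotone knee-flexion descent reaching the target
#' peak angle exactly at the end of the descending phase, superimposed sway
#' whose extracted path/ellipse parameters match the targets, then an
#' ascent. Calibrated against the package's own extraction chain.
#'
#' @param recipe a [sway_recipe()] with task `"SLS"`.
#' @return list with `trial`, `static` and `targets`.
#' @export
synthesize_squat_trial <- function(recipe) {
  stopifnot(inherits(recipe, "sway_recipe"), recipe$task == "SLS")
  tg <- recipe$targets
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(recipe$seed)

  static <- synthesize_static_trial(
    1.5, recipe$sample_rate, recipe$mount_tilt_deg,
    recipe$noise_gyro_dps, recipe$noise_accel,
    seed = recipe$seed + 2000003L)

  t_ramp <- tg$t_dp
  theta_max <- tg$theta_ymax
  # raw (window-total) budgets; the outer loop rescales them to absorb the
  # start-detection delay and estimation bias seen by the real extractor
  budget <- c(ml = tg$pl_ml * tg$t_dp, ap = tg$pl_ap * tg$t_dp,
              ea = tg$ea * tg$t_dp, pl = tg$pl * tg$t_dp)

  trial <- NULL
  lambda_fixed <- NULL
  for (it in 1:8) {
    n_ramp <- round(t_ramp * recipe$sample_rate) + 1
    osc <- design_squat_osc(n_ramp, theta_max, budget[["ml"]],
                            budget[["ap"]], budget[["ea"]], recipe$level,
                            l_pl = budget[["pl"]], lambda_fixed = lambda_fixed)
    lambda_fixed <- osc$lambda
    trial <- build_squat_signals(recipe, t_ramp, theta_max, osc$dip_amp,
                                 osc$ap_amp, osc$n_cyc, osc$lambda)
    feats <- extract_squat_features(trial, static, level = recipe$level)
    rel <- function(x, t) if (abs(t) > 1e-12) x / t else 1
    errs <- c(
      tdp = feats$sls_t_dp - tg$t_dp,
      th = feats$sls_theta_ymax - tg$theta_ymax,
      ml = rel(feats$sls_pl_ml, tg$pl_ml), ap = rel(feats$sls_pl_ap, tg$pl_ap),
      ea = rel(feats$sls_ea, tg$ea)
    )
    ok <- abs(errs[["tdp"]]) < 0.02 && abs(errs[["th"]]) < 0.2 &&
      all(abs(errs[c("ml", "ap", "ea")] - 1) < 0.02)
    if (ok) break
    t_ramp <- t_ramp + (tg$t_dp - feats$sls_t_dp)
    theta_max <- theta_max + (tg$theta_ymax - feats$sls_theta_ymax)
    # damped multiplicative steps: the detected window shifts with the
    # design, so full-step corrections overshoot
    clampf <- function(e) min(max(e, 0.5), 2)^0.7
    budget[["ml"]] <- budget[["ml"]] / clampf(errs[["ml"]])
    budget[["ap"]] <- budget[["ap"]] / clampf(errs[["ap"]])
    budget[["ea"]] <- budget[["ea"]] / clampf(errs[["ea"]])
  }
  list(trial = trial, static = static,
       targets = tibble(
         sls_t_dp = tg$t_dp, sls_pl = tg$pl, sls_pl_ap = tg$pl_ap,
         sls_pl_ml = tg$pl_ml, sls_ea = tg$ea,
         sls_theta_ymax = tg$theta_ymax))
}
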