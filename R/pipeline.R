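#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline; every default restates the
#' module-level default it controls. The configuration round-trips through
#' YAML unchanged.
#'
#' @param ... named overrides, e.g. `cohort = list(n_nr = 10, n_r = 5)`
#'   (partial lists are merged over the defaults).
#' @return a list of class `sway_config`.
#' @export
sway_config <- function(...) {
  cfg <- list(
    seed = 1L,
    mode = "feature", # "feature" or "signal"
    cohort = list(n_nr = 26L, n_r = 13L, corr_block = 0.7, corr_base = 0.2),
    less = list(mean_nr = 3.5, mean_r = 7.5, rho = 0.88),
    signal = list(sample_rate = 100, mount_tilt_deg = 2,
                  noise_gyro_dps = 0.2, noise_accel = 0.03, n_reps = 5L),
    orientation = list(kp = 1.0, ki = 0.3, accel_gate = 0.4, depth_cm = 1.0),
    events = list(cutoff_hz = 10, k = 5.0, win_s = 0.5),
    features = list(level = 0.99),
    bench = list(scheme = "grouped-9fold", n_folds = 9L),
    importance = list(n_trees = 500L, threshold = 15.0, n_repeats = 1L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("sway_config", "list"))
}

#' @rdname sway_config
#' @param path YAML file path.
#' @export
read_sway_config <- function(path) {
  do.call(sway_config, yaml::read_yaml(path))
}

#' @rdname sway_config
#' @param config a `sway_config`.
#' @export
write_sway_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

# deterministic per-stage seeds below 2^31
stage_seed <- function(seed, stage) {
  offs <- c(cohort = 101L, less = 211L, signal = 307L, bench = 401L,
            importance = 503L)
  (as.integer(seed) * 97L + offs[[stage]]) %% 2000000011L
}

# synthesize and extract one athlete's 13 features from signal-level trials
signal_athlete_features <- function(feature_row, cfg, seed) {
  v <- stats::setNames(as.numeric(feature_row[acl_feature_names()]),
                       acl_feature_names())
  dur <- v[["mcmj_ts"]]
  pl_m <- reconcile_path_targets(v[["mcmj_pl"]] * dur, v[["mcmj_pl_ap"]] * dur,
                                 v[["mcmj_pl_ml"]] * dur) / dur
  rec_j <- sway_recipe("mCMJ", list(
    ts = v[["mcmj_ts"]], pl = pl_m, pl_ap = v[["mcmj_pl_ap"]],
    pl_ml = v[["mcmj_pl_ml"]], ea = v[["mcmj_ea"]],
    rms_z = v[["mcmj_rms_z"]], rms_xy = v[["mcmj_rms_xy"]]),
    sample_rate = cfg$signal$sample_rate, seed = seed,
    mount_tilt_deg = cfg$signal$mount_tilt_deg,
    noise_gyro_dps = cfg$signal$noise_gyro_dps,
    noise_accel = cfg$signal$noise_accel)
  dur <- v[["sls_t_dp"]]
  pl_s <- reconcile_path_targets(v[["sls_pl"]] * dur, v[["sls_pl_ap"]] * dur,
                                 v[["sls_pl_ml"]] * dur) / dur
  rec_s <- sway_recipe("SLS", list(
    t_dp = v[["sls_t_dp"]], pl = pl_s, pl_ap = v[["sls_pl_ap"]],
    pl_ml = v[["sls_pl_ml"]], ea = v[["sls_ea"]],
    theta_ymax = v[["sls_theta_ymax"]]),
    sample_rate = cfg$signal$sample_rate, seed = seed + 1L,
    mount_tilt_deg = cfg$signal$mount_tilt_deg,
    noise_gyro_dps = cfg$signal$noise_gyro_dps,
    noise_accel = cfg$signal$noise_accel)
  n_reps <- cfg$signal$n_reps
  mcmj <- purrr::map(seq_len(n_reps), function(r) {
    rec <- rec_j; rec$seed <- rec_j$seed + 10L * r
    out <- synthesize_jump_trial(rec)
    extract_jump_features(out$trial, out$led, out$static,
                          level = cfg$features$level,
                          kp = cfg$orientation$kp, ki = cfg$orientation$ki,
                          accel_gate = cfg$orientation$accel_gate,
                          cutoff_hz = cfg$events$cutoff_hz,
                          depth_cm = cfg$orientation$depth_cm)
  }) |> purrr::list_rbind()
  sls <- purrr::map(seq_len(n_reps), function(r) {
    rec <- rec_s; rec$seed <- rec_s$seed + 10L * r
    out <- synthesize_squat_trial(rec)
    extract_squat_features(out$trial, out$static,
                           level = cfg$features$level,
                           k = cfg$events$k, win_s = cfg$events$win_s,
                           kp = cfg$orientation$kp, ki = cfg$orientation$ki,
                           accel_gate = cfg$orientation$accel_gate,
                           depth_cm = cfg$orientation$depth_cm)
  }) |> purrr::list_rbind()
  build_feature_vector(mcmj, sls, allow_fewer = TRUE)
}

#' Run the full pipeline
#'
#' Feature mode samples a feature-level cohort from the group models, builds
#' LESS records coupled to the jump ellipse area, benchmarks the nine
#' classifiers against the LESS-derived labels and computes permutation
#' importances plus the correlation of above-threshold features with the
#' LESS score. Signal mode additionally pushes every athlete's feature row
#' through the signal-level generator and the full
#' orientation/events/features extraction chain before benchmarking (use
#' small cohorts: each athlete synthesizes `2 * n_reps` trials).
#'
#' @param config a [sway_config()].
#' @return object of class `sway_report`: list with `features` (tibble),
#'   `less` (records), `bench` (`sway_bench`), `importance`
#'   (`sway_importance`), `correlations` (tibble), `config`.
#' @export
run_pipeline <- function(config = sway_config()) {
  cfg <- config
  corr <- default_feature_correlation(cfg$cohort$corr_block,
                                      cfg$cohort$corr_base)
  cohort <- sample_feature_cohort(cfg$cohort$n_nr, cfg$cohort$n_r,
                                  default_group_models(corr),
                                  seed = stage_seed(cfg$seed, "cohort"))
  feats <- cohort$features
  if (identical(cfg$mode, "signal")) {
    sseed <- stage_seed(cfg$seed, "signal")
    rows <- purrr::map(seq_len(nrow(feats)), function(i) {
      signal_athlete_features(feats[i, ], cfg, seed = sseed + 1000L * i)
    }) |> purrr::list_rbind()
    feats <- dplyr::bind_cols(feats[, c("athlete_id", "label")], rows)
  }
  less <- generate_less_records(
    feats$label, feats$mcmj_ea,
    target_means = c(NR = cfg$less$mean_nr, R = cfg$less$mean_r),
    target_rho = cfg$less$rho, seed = stage_seed(cfg$seed, "less"))
  labels <- less$records$label[match(feats$athlete_id,
                                     less$records$athlete_id)]
  bench <- run_bench(feats, labels, scheme = cfg$bench$scheme,
                     n_folds = cfg$bench$n_folds,
                     seed = stage_seed(cfg$seed, "bench"))
  imp <- mda_importance(feats, labels, n_trees = cfg$importance$n_trees,
                        seed = stage_seed(cfg$seed, "importance"),
                        n_repeats = cfg$importance$n_repeats,
                        threshold = cfg$importance$threshold)
  top <- imp$importance$feature[imp$importance$mda >= cfg$importance$threshold]
  if (length(top) == 0) {
    # with strongly redundant features the importance mass is shared and no
    # single feature may clear the threshold: correlate the top four instead
    top <- imp$importance$feature[imp$importance$rank <= 4]
  }
  med <- less$records$median_score[match(feats$athlete_id,
                                         less$records$athlete_id)]
  correlations <- purrr::map(top, function(f) {
    dplyr::mutate(spearman_band(feats[[f]], med), feature = f, .before = 1)
  }) |> purrr::list_rbind()
  structure(list(features = feats, less = less$records, bench = bench,
                 importance = imp, correlations = correlations,
                 config = cfg),
            class = "sway_report")
}

#' Text summary of a pipeline report
#'
#' Renders the per-classifier metric table (accuracy, F1, goodness index,
#' category) and the feature-LESS correlation table as plain text.
#'
#' @param object a `sway_report`.
#' @param ... unused.
#' @return the lines, invisibly; printed as a side effect.
#' @export
summary.sway_report <- function(object, ...) {
  if (is.null(object$bench) || nrow(object$bench$metrics) == 0) {
    abort_swayrisk("empty benchmark: nothing to summarize")
  }
  m <- object$bench$metrics
  lines <- c(
    sprintf("Cohort: %d athletes (%d NR / %d R), mode = %s",
            nrow(object$features), sum(object$features$label == "NR"),
            sum(object$features$label == "R"), object$config$mode),
    "",
    "Classifier performance (pooled cross-validation):",
    sprintf("  %-6s %5s %5s %5s  %s", "id", "A", "F1", "G", "category"),
    sprintf("  %-6s %5.2f %5.2f %5.2f  %s", m$id, m$accuracy, m$f1, m$g,
            as.character(m$category)),
    ""
  )
  if (!is.null(object$correlations) && nrow(object$correlations) > 0) {
    cc <- object$correlations
    lines <- c(lines,
      "Correlation of important features with the LESS score:",
      sprintf("  %-14s %6s %8s  %s", "feature", "r", "p", "band"),
      sprintf("  %-14s %6.2f %8.3g  %s", cc$feature, cc$r, cc$p_value,
              as.character(cc$band)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.sway_report <- function(x, ...) {
  summary.sway_report(x)
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' Columns: `athlete_id`, `label`, then the 13 features in canonical order.
#'
#' @param features tibble as in a `sway_report`.
#' @param path file path.
#' @return the tibble read, or the input invisibly.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(features)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if ("label" %in% names(x)) x$label <- factor(x$label, levels = c("NR", "R"))
  x
}

#' Write a pipeline report as a JSON + CSV bundle
#'
#' @param report a `sway_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_features_csv(report$features, file.path(dir, "features.csv"))
  readr::write_csv(report$less, file.path(dir, "less_records.csv"))
  readr::write_csv(report$bench$metrics, file.path(dir, "bench_metrics.csv"))
  readr::write_csv(report$importance$importance,
                   file.path(dir, "importance.csv"))
  if (nrow(report$correlations) > 0) {
    readr::write_csv(report$correlations, file.path(dir, "correlations.csv"))
  }
  jsonlite::write_json(
    list(config = unclass(report$config),
         bench = list(scheme = report$bench$scheme, seed = report$bench$seed),
         n_athletes = nrow(report$features)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Sway-path plot for a trial
#'
#' @param path a `sway_path`.
#' @param window optional time window.
#' @return a ggplot object.
#' @export
plot_sway_path <- function(path, window = NULL) {
  p <- path_window(path, window)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$ml_cm, y = .data$ap_cm)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ML (cm)", y = "AP (cm)",
                  title = "Projected vertical-axis sway path") +
    ggplot2::theme_minimal()
}
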