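#' Published group feature models (means and SDs)
#'
#' Per-group mean and SD of the 13 features on the time-normalized scale, as
#' reported for the at-risk (R) and not-at-risk (NR) cohorts of 13 and 26
#' female basketball players. Units follow the reported labels (cm, cm^2,
#' m/s^2, s, degrees) even though time-normalization changes dimensions, for
#' comparability.
#'
#' @return tibble with columns `feature`, `r_mean`, `r_sd`, `nr_mean`,
#'   `nr_sd`, ordered as [acl_feature_names()].
#' @export
acl_group_models <- function() {
  tibble(
    feature = acl_feature_names(),
    r_mean = c(0.21, 2.7, 1.5, 2.8, 1.5, 247.4, 169.4,
               3.22, 0.8, 0.6, 0.4, 0.5, 16.8),
    r_sd   = c(0.04, 0.9, 0.5, 0.2, 0.2, 85.6, 26.7,
               0.95, 0.1, 0.1, 0.1, 0.0, 2.7),
    nr_mean = c(0.33, 2.9, 1.6, 1.1, 0.7, 95.6, 70.1,
                3.90, 0.8, 0.6, 0.5, 0.7, 26.0),
    nr_sd  = c(0.06, 0.8, 0.3, 0.1, 0.2, 19.4, 14.9,
               1.23, 0.3, 0.2, 0.2, 0.0, 5.3)
  )
}

#' Default inter-feature correlation matrix
#'
#' Within-task jump instability features (`mcmj_pl_ml`, `mcmj_ea`,
#' `mcmj_rms_z`, `mcmj_rms_xy`) are strongly redundant (pairwise r = 0.7 by
#' default); all other pairs share a mild positive correlation (0.2). The
#' published importances are only consistent with strong redundancy among
#' the highly separating jump features (several show > 4 SD univariate
#' separation yet small permutation importance), hence the block structure.
#'
#' @param r_block correlation within the jump-instability block.
#' @param r_base correlation between all other pairs.
#' @return a 13 x 13 correlation matrix with unit diagonal.
#' @export
default_feature_correlation <- function(r_block = 0.7, r_base = 0.2) {
  nm <- acl_feature_names()
  p <- length(nm)
  corr <- matrix(r_base, p, p, dimnames = list(nm, nm))
  block <- c("mcmj_pl_ml", "mcmj_ea", "mcmj_rms_z", "mcmj_rms_xy")
  corr[block, block] <- r_block
  diag(corr) <- 1
  corr
}

#' Build a group feature model
#'
#' @param group_label `"R"` or `"NR"`.
#' @param mean,sd numeric vectors of length 13 in [acl_feature_names()]
#'   order; all SDs must be nonnegative.
#' @param corr 13 x 13 positive-semidefinite correlation matrix (unit
#'   diagonal).
#' @return a list of class `group_feature_model`.
#' @export
group_feature_model <- function(group_label, mean, sd,
                                corr = default_feature_correlation()) {
  stopifnot(group_label %in% c("R", "NR"))
  if (length(mean) != 13 || length(sd) != 13) {
    abort_swayrisk("mean and sd must have exactly 13 entries")
  }
  if (any(sd < 0)) abort_swayrisk("all sd must be nonnegative")
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(unname(diag(corr)), rep(1, 13), tolerance = 1e-8))) {
    abort_swayrisk("correlation matrix must have unit diagonal",
                   class = "swayrisk_config_error")
  }
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    abort_swayrisk("correlation matrix must be symmetric",
                   class = "swayrisk_config_error")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) {
    abort_swayrisk("correlation matrix is not positive semidefinite",
                   class = "swayrisk_config_error")
  }
  structure(list(group_label = group_label, mean = as.numeric(mean),
                 sd = as.numeric(sd), corr = corr),
            class = "group_feature_model")
}

#' The pair of published group models
#'
#' @param corr correlation matrix shared by both groups.
#' @return named list with elements `NR` and `R` of
#'   [group_feature_model()]s parameterized from [acl_group_models()].
#' @export
default_group_models <- function(corr = default_feature_correlation()) {
  tab <- acl_group_models()
  list(
    NR = group_feature_model("NR", tab$nr_mean, tab$nr_sd, corr),
    R = group_feature_model("R", tab$r_mean, tab$r_sd, corr)
  )
}
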