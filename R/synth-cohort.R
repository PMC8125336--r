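# ---- feature-level synthetic cohorts ---------------------------------------

# draw n rows from a group model; whole rows violating nonnegativity are
# rejected and resampled so nonnegative features carry no point mass at 0
sample_group_rows <- function(n, model) {
  p <- length(model$mean)
  sigma <- diag(model$sd, p) %*% model$corr %*% diag(model$sd, p)
  out <- matrix(NA_real_, 0, p)
  guard <- 0
  while (nrow(out) < n) {
    m <- max(n - nrow(out), 8)
    draw <- MASS::mvrnorm(m, mu = model$mean, Sigma = sigma)
    if (m == 1) draw <- matrix(draw, nrow = 1)
    keep <- apply(draw, 1, function(r) all(r >= 0))
    out <- rbind(out, draw[keep, , drop = FALSE])
    guard <- guard + 1
    if (guard > 1000) {
      abort_swayrisk("rejection sampling failed: model mass is mostly negative")
    }
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- acl_feature_names()
  out
}

#' Sample a feature-level synthetic cohort
#'
#' Draws each athlete's 13-feature row from the group's multivariate Gaussian
#' (published group means/SDs with the configured inter-feature correlation),
#' rejecting whole rows with any negative entry. Reproducible under a fixed
#' seed.
#'
#' @param n_nr,n_r number of not-at-risk and at-risk athletes (both >= 1).
#' @param models named list with `NR` and `R` [group_feature_model()]s
#'   (defaults to the published models).
#' @param seed integer seed.
#' @return a list of class `synthetic_cohort`: `features` (tibble with
#'   `athlete_id`, `label` and the 13 feature columns) and `seed`. LESS
#'   records can be attached with [generate_less_records()].
#' @export
#' @examples
#' cohort <- sample_feature_cohort(26, 13, seed = 1)
#' dplyr::count(cohort$features, label)
sample_feature_cohort <- function(n_nr, n_r, models = default_group_models(),
                                  seed = 1) {
  if (n_nr < 1 || n_r < 1) abort_swayrisk("need at least 1 athlete per group")
  stopifnot(all(c("NR", "R") %in% names(models)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nr_rows <- sample_group_rows(n_nr, models$NR)
  r_rows <- sample_group_rows(n_r, models$R)
  feats <- as_tibble(rbind(nr_rows, r_rows))
  feats <- dplyr::bind_cols(
    tibble(
      athlete_id = sprintf("ath%04d", seq_len(n_nr + n_r)),
      label = factor(rep(c("NR", "R"), c(n_nr, n_r)), levels = c("NR", "R"))
    ),
    feats
  )
  structure(list(features = feats, seed = seed), class = "synthetic_cohort")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- LESS record generation -------------------------------------------------

# integer median-score distribution for a group: NR scores live in 0..5,
# R scores in 6..19; a (shifted) binomial matches the requested group mean
group_score_sampler <- function(group, target_mean) {
  if (group == "NR") {
    if (target_mean < 0 || target_mean > 5) {
      abort_swayrisk("NR mean LESS score must lie in [0, 5] (median <= 5 rule)",
                     class = "swayrisk_config_error")
    }
    list(lo = 0L, size = 5L, p = target_mean / 5)
  } else {
    if (target_mean < 6 || target_mean > 19) {
      abort_swayrisk("R mean LESS score must lie in [6, 19] (median > 5 rule)",
                     class = "swayrisk_config_error")
    }
    list(lo = 6L, size = 13L, p = (target_mean - 6) / 13)
  }
}

# quantile-map standard-normal latents to group-constrained integer scores
latent_to_scores <- function(z, sampler) {
  u <- stats::pnorm(z)
  sampler$lo + stats::qbinom(u, sampler$size, sampler$p)
}

#' @importFrom stats qbinom
NULL

# latent severity: the athlete's EA percentile *within their group* (so the
# group score distributions stay calibrated), blended with independent noise
group_latent <- function(labels, ea, eps, rho_l) {
  z <- numeric(length(ea))
  for (g in c("NR", "R")) {
    i <- which(labels == g)
    if (length(i) > 0) {
      z_ea <- stats::qnorm((rank(ea[i]) - 0.5) / length(i))
      z[i] <- rho_l * z_ea + sqrt(max(0, 1 - rho_l^2)) * eps[i]
    }
  }
  z
}

# overall Spearman between ea and the generated median scores for a given
# latent coupling rho_l, estimated on a large internal pilot population
pilot_spearman <- function(rho_l, labels, ea, eps, samplers) {
  z <- group_latent(labels, ea, eps, rho_l)
  score <- numeric(length(ea))
  for (g in c("NR", "R")) {
    i <- which(labels == g)
    if (length(i) > 0) score[i] <- latent_to_scores(z[i], samplers[[g]])
  }
  stats::cor(ea, score, method = "spearman")
}

# decompose a jump score into 17 item scores: choose `score` of the 19
# available unit slots (items 16/17 own two slots each) uniformly at random
decompose_score <- function(score) {
  slots <- c(1:15, 16L, 16L, 17L, 17L)
  chosen <- sample(slots, score, replace = FALSE)
  items <- tabulate(chosen, nbins = 17L)
  as.integer(items)
}

#' Generate LESS records coupled to the jump ellipse area
#'
#' Produces three 17-item jump scorings per athlete such that (i) every item
#' respects its allowed range, (ii) the median jump score is <= 5 for NR
#' athletes and > 5 for R athletes, (iii) group means of the median score
#' match `target_means`, and (iv) the rank correlation between the athlete's
#' jump ellipse area (`ea`) and the median score approaches `target_rho`.
#' The coupling uses a Gaussian copula whose latent strength is chosen by a
#' seeded internal pilot simulation, so the requested Spearman correlation is
#' attained after integer quantization and the group threshold constraints.
#'
#' @param labels factor of athlete labels (`NR`/`R`).
#' @param ea numeric vector of jump ellipse areas, one per athlete (drives
#'   the rank coupling).
#' @param target_means named numeric: mean median-score per group
#'   (`c(NR = 3.5, R = 7.5)` by default).
#' @param target_rho desired Spearman correlation between `ea` and the
#'   median score, in [-1, 1].
#' @param seed integer seed.
#' @return a list: `items` (tibble, one row per athlete x jump with
#'   `athlete_id`, `jump`, `item_1..item_17`) and `records` (per-athlete
#'   tibble from [less_records()]).
#' @export
generate_less_records <- function(labels, ea,
                                  target_means = c(NR = 3.5, R = 7.5),
                                  target_rho = 0.88, seed = 1) {
  n <- length(labels)
  stopifnot(length(ea) == n)
  if (abs(target_rho) > 1) abort_swayrisk("|target_rho| must be <= 1")
  labels <- factor(labels, levels = c("NR", "R"))
  samplers <- list(NR = group_score_sampler("NR", target_means[["NR"]]),
                   R = group_score_sampler("R", target_means[["R"]]))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # pilot calibration of the latent copula strength on a large synthetic
  # population with the same group proportions and EA model
  rho_l <- 0
  if (abs(target_rho) > 1e-12) {
    npilot <- 2000
    prop_r <- max(1, round(npilot * mean(labels == "R", na.rm = TRUE)))
    lab_p <- factor(rep(c("NR", "R"), c(npilot - prop_r, prop_r)),
                    levels = c("NR", "R"))
    tab <- acl_group_models()
    ea_mu <- ifelse(lab_p == "R", tab$r_mean[tab$feature == "mcmj_ea"],
                    tab$nr_mean[tab$feature == "mcmj_ea"])
    ea_sd <- ifelse(lab_p == "R", tab$r_sd[tab$feature == "mcmj_ea"],
                    tab$nr_sd[tab$feature == "mcmj_ea"])
    ea_p <- stats::rnorm(npilot, ea_mu, ea_sd)
    eps_p <- stats::rnorm(npilot)
    grid <- seq(0, 1, by = 0.05)
    rho_hat <- vapply(grid, pilot_spearman, numeric(1),
                      labels = lab_p, ea = ea_p, eps = eps_p,
                      samplers = samplers)
    tgt <- abs(target_rho)
    if (tgt >= max(rho_hat)) {
      rho_l <- 1
    } else {
      rho_l <- stats::approx(rho_hat, grid, xout = tgt, ties = "ordered")$y
    }
    rho_l <- sign(target_rho) * min(1, max(0, rho_l))
  }

  # latent severity coupled to the athlete's within-group EA percentile
  z <- group_latent(labels, ea, stats::rnorm(n), rho_l)
  med <- integer(n)
  for (g in c("NR", "R")) {
    i <- which(labels == g)
    if (length(i) > 0) med[i] <- latent_to_scores(z[i], samplers[[g]])
  }

  # three jump scores with the prescribed median: one at the median, one not
  # above, one not below; jitter scales with the group score spread so a
  # degenerate target (e.g. mean 0) yields identical jumps
  jmax <- vapply(samplers, function(s) {
    min(2L, as.integer(ceiling(2 * sqrt(s$size * s$p * (1 - s$p)))))
  }, integer(1))
  items_rows <- vector("list", n * 3)
  for (i in seq_len(n)) {
    m <- med[i]
    jm <- jmax[[as.character(labels[i])]]
    lo <- max(0L, m - sample(0:jm, 1))
    hi <- min(19L, m + sample(0:jm, 1))
    jumps <- sample(c(m, lo, hi))
    for (j in 1:3) {
      items_rows[[(i - 1) * 3 + j]] <- c(i, j, decompose_score(jumps[j]))
    }
  }
  items <- as.data.frame(do.call(rbind, items_rows))
  names(items) <- c("athlete", "jump", paste0("item_", 1:17))
  items <- as_tibble(items) |>
    dplyr::mutate(athlete_id = sprintf("ath%04d", .data$athlete),
                  .before = 1) |>
    dplyr::select(-"athlete")
  records <- less_records(items)
  list(items = items, records = records)
}
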