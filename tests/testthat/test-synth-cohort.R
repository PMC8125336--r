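test_that("feature cohorts have the requested composition and are seeded", {
  co <- sample_feature_cohort(26, 13, seed = 1)
  expect_equal(nrow(co$features), 39)
  expect_equal(sum(co$features$label == "NR"), 26)
  expect_equal(sum(co$features$label == "R"), 13)
  expect_true(all(as.matrix(co$features[, acl_feature_names()]) >= 0))

  co2 <- sample_feature_cohort(26, 13, seed = 1)
  expect_identical(co$features, co2$features)
  co3 <- sample_feature_cohort(26, 13, seed = 2)
  expect_false(identical(co$features, co3$features))
})

test_that("degenerate models (all sd = 0) reproduce the group means", {
  tab <- acl_group_models()
  models <- list(
    NR = group_feature_model("NR", tab$nr_mean, rep(0, 13)),
    R = group_feature_model("R", tab$r_mean, rep(0, 13))
  )
  co <- sample_feature_cohort(1, 1, models, seed = 99)
  expect_equal(as.numeric(co$features[1, acl_feature_names()]), tab$nr_mean,
               tolerance = 1e-9)
  expect_equal(as.numeric(co$features[2, acl_feature_names()]), tab$r_mean,
               tolerance = 1e-9)
})

test_that("empirical moments converge to the model parameters", {
  co <- sample_feature_cohort(1000, 1000, seed = 7)
  tab <- acl_group_models()
  x <- co$features
  for (j in seq_len(13)) {
    f <- tab$feature[j]
    if (tab$nr_sd[j] > 0) {
      expect_rel_equal(sd(x[[f]][x$label == "NR"]), tab$nr_sd[j], 0.05)
      expect_rel_equal(mean(x[[f]][x$label == "NR"]), tab$nr_mean[j], 0.05)
    }
    if (tab$r_sd[j] > 0) {
      expect_rel_equal(sd(x[[f]][x$label == "R"]), tab$r_sd[j], 0.05)
    }
  }
})

test_that("invalid correlation matrices are configuration errors", {
  bad <- default_feature_correlation()
  bad[1, 2] <- 0.9 # asymmetric
  expect_error(group_feature_model("NR", acl_group_models()$nr_mean,
                                   acl_group_models()$nr_sd, bad),
               class = "swayrisk_config_error")
  bad2 <- matrix(0.99, 13, 13); diag(bad2) <- 1
  bad2[1, 2] <- bad2[2, 1] <- -0.99 # indefinite
  expect_error(group_feature_model("NR", acl_group_models()$nr_mean,
                                   acl_group_models()$nr_sd, bad2),
               class = "swayrisk_config_error")
})

test_that("LESS generation respects ranges, thresholds and group means", {
  co <- sample_feature_cohort(26, 13, seed = 3)
  g <- generate_less_records(co$features$label, co$features$mcmj_ea, seed = 3)
  items <- as.matrix(g$items[, paste0("item_", 1:17)])
  rng <- less_item_ranges()$max_score
  for (i in 1:17) {
    expect_true(all(items[, i] >= 0 & items[, i] <= rng[i]))
  }
  expect_true(all(g$records$score_1 <= 19))
  # every NR median <= 5, every R median >= 6
  expect_true(all(g$records$median_score[co$features$label == "NR"] <= 5))
  expect_true(all(g$records$median_score[co$features$label == "R"] >= 6))
  expect_equal(as.character(g$records$label),
               as.character(co$features$label))
  # group means near their targets (small-sample slack)
  means <- tapply(g$records$median_score, co$features$label, mean)
  expect_lt(abs(means[["NR"]] - 3.5), 0.8)
  expect_lt(abs(means[["R"]] - 7.5), 1.2)
})

test_that("degenerate LESS targets give all-zero items", {
  labs <- factor(rep("NR", 10), levels = c("NR", "R"))
  g <- generate_less_records(labs, runif(10), target_means = c(NR = 0, R = 7),
                             target_rho = 0, seed = 1)
  expect_true(all(as.matrix(g$items[, paste0("item_", 1:17)]) == 0))
  expect_true(all(g$records$median_score == 0))
})

test_that("unreachable group means error", {
  labs <- factor(c("NR", "R"), levels = c("NR", "R"))
  expect_error(generate_less_records(labs, c(1, 2),
                                     target_means = c(NR = 7, R = 8)),
               class = "swayrisk_config_error")
  expect_error(generate_less_records(labs, c(1, 2),
                                     target_means = c(NR = 3, R = 4)),
               class = "swayrisk_config_error")
})

test_that("the EA-score rank correlation is recovered at scale", {
  co <- sample_feature_cohort(200, 100, seed = 5)
  g <- generate_less_records(co$features$label, co$features$mcmj_ea,
                             target_rho = 0.88, seed = 5)
  r <- cor(co$features$mcmj_ea, g$records$median_score, method = "spearman")
  expect_lt(abs(r - 0.88), 0.1)
})
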