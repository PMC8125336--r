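test_that("irrelevant features have near-zero importance, separators rank first", {
  withr::with_seed(9, {
    n <- 120
    x <- tibble::tibble(
      sep = c(rnorm(n / 2, -2, 0.5), rnorm(n / 2, 2, 0.5)),
      noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n)
    )
    y <- factor(rep(c("NR", "R"), each = n / 2))
  })
  imp <- mda_importance(x, y, n_trees = 500, seed = 2)
  tab <- imp$importance
  expect_equal(tab$feature[tab$rank == 1], "sep")
  for (f in c("noise1", "noise2", "noise3")) {
    expect_lt(abs(tab$mda[tab$feature == f]), 2)
  }
  expect_gt(tab$mda[tab$feature == "sep"], 15)
  # the ranking is a permutation of the features
  expect_setequal(tab$rank, 1:4)
})

test_that("the in-package MDA agrees with the reference forest importance", {
  withr::with_seed(9, {
    n <- 120
    x <- tibble::tibble(
      sep = c(rnorm(n / 2, -2, 0.5), rnorm(n / 2, 2, 0.5)),
      noise1 = rnorm(n), noise2 = rnorm(n)
    )
    y <- factor(rep(c("NR", "R"), each = n / 2))
  })
  imp <- mda_importance(x, y, n_trees = 500, seed = 2)
  set.seed(2)
  rf <- randomForest::randomForest(as.data.frame(x), y, ntree = 500,
                                   importance = TRUE)
  ref <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1] * 100
  expect_equal(imp$importance$mda, unname(ref[imp$importance$feature]),
               tolerance = 0.15)
})

test_that("duplicating an informative feature dilutes its importance", {
  withr::with_seed(21, {
    n <- 150
    x <- tibble::tibble(
      sep = c(rnorm(n / 2, -1.5, 1), rnorm(n / 2, 1.5, 1)),
      noise = rnorm(n)
    )
    y <- factor(rep(c("NR", "R"), each = n / 2))
  })
  solo <- mda_importance(x, y, n_trees = 500, seed = 3)
  dup <- mda_importance(dplyr::mutate(x, sep_copy = x$sep), y,
                        n_trees = 500, seed = 3)
  mda_solo <- solo$importance$mda[solo$importance$feature == "sep"]
  expect_lt(dup$importance$mda[dup$importance$feature == "sep"], mda_solo)
  expect_lt(dup$importance$mda[dup$importance$feature == "sep_copy"], mda_solo)
})

test_that("zero-variance features get zero importance with a warning", {
  withr::with_seed(4, {
    x <- tibble::tibble(a = rnorm(60), flat = rep(1, 60))
    y <- factor(rep(c("NR", "R"), each = 30))
  })
  expect_warning(imp <- mda_importance(x, y, n_trees = 60, seed = 1), "flat")
  expect_equal(imp$importance$mda[imp$importance$feature == "flat"], 0)
})

test_that("importance is deterministic under a fixed seed", {
  toy <- toy_separable(25, sd = 2, seed = 10)
  i1 <- mda_importance(toy$x, toy$y, n_trees = 100, seed = 5)
  i2 <- mda_importance(toy$x, toy$y, n_trees = 100, seed = 5)
  expect_identical(i1$importance, i2$importance)
})

test_that("spearman_band reports exact correlations and bands", {
  expect_equal(spearman_band(1:10, (1:10)^3)$r, 1)
  expect_equal(as.character(spearman_band(1:10, (1:10)^3)$band), "perfect")
  expect_equal(spearman_band(1:10, -(1:10))$r, -1)
  withr::with_seed(2, {
    x <- rnorm(100); y <- rnorm(100)
  })
  out <- spearman_band(x, y)
  expect_lt(abs(out$r), 0.3)
  expect_error(spearman_band(rep(1, 10), 1:10), "constant")
  expect_error(spearman_band(1:3, 1:3), ">= 5")
})

test_that("spearman_band is invariant under strictly monotone transforms", {
  withr::with_seed(11, {
    x <- rnorm(50); y <- x + rnorm(50)
  })
  base <- spearman_band(x, y)
  expect_equal(spearman_band(exp(x), y)$r, base$r)
  expect_equal(spearman_band(x, y^3 + 5 * y)$r, base$r)
  expect_equal(spearman_band(rank(x), y)$r, base$r)
})

test_that("band boundaries are assigned to the lower band", {
  # construct rank-exact correlations: r = 1 - 6*S/(n^3-n)
  # with n = 5 and one adjacent swap: r = 0.9 -> strong
  expect_equal(as.character(spearman_band(1:5, c(2, 1, 3, 4, 5))$band),
               "strong")
  # anticorrelation magnitude in the moderate band
  withr::with_seed(3, {
    x <- 1:200
    y <- -x + rnorm(200, sd = 150)
  })
  out <- spearman_band(x, y)
  expect_true(abs(out$r) > 0.3 && abs(out$r) <= 0.75)
})
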