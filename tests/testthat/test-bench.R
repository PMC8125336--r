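test_that("metric formulas match hand arithmetic", {
  cm <- tibble::tibble(tp = 20, tn = 10, fp = 6, fn = 3)
  expect_equal(accuracy(cm), 30 / 39)
  re <- 20 / 23; pr <- 20 / 26
  expect_equal(f1_score(cm), 2 * re * pr / (re + pr))
  expect_equal(g_index(cm), sqrt((1 - 20 / 23)^2 + (1 - 10 / 16)^2))

  perfect <- tibble::tibble(tp = 26, tn = 13, fp = 0, fn = 0)
  expect_equal(accuracy(perfect), 1)
  expect_equal(f1_score(perfect), 1)
  expect_equal(g_index(perfect), 0)

  wrong <- tibble::tibble(tp = 0, tn = 0, fp = 26, fn = 13)
  expect_equal(accuracy(wrong), 0)
  expect_equal(f1_score(wrong), 0)
  expect_equal(g_index(wrong), sqrt(2))

  # chance classifier: both rates 0.5 -> G = sqrt(0.5), the 0.70 boundary
  half <- tibble::tibble(tp = 5, tn = 5, fp = 5, fn = 5)
  expect_equal(g_index(half), sqrt(0.5))
})

test_that("FP/FN asymmetry is carried by G, not by accuracy or F1", {
  # F1 reduces to 2TP / (2TP + FP + FN), so like accuracy it is symmetric
  # in the two error kinds; the goodness index separates sensitivity from
  # specificity and is not
  cm <- tibble::tibble(tp = 20, tn = 10, fp = 6, fn = 3)
  sw <- tibble::tibble(tp = 20, tn = 10, fp = 3, fn = 6)
  expect_equal(accuracy(cm), accuracy(sw))
  expect_equal(f1_score(cm), 2 * 20 / (2 * 20 + 6 + 3))
  expect_equal(f1_score(cm), f1_score(sw))
  expect_false(isTRUE(all.equal(g_index(cm), g_index(sw))))
  # swapping the positive-class convention does change F1
  flipped <- tibble::tibble(tp = 10, tn = 20, fp = 3, fn = 6)
  expect_false(isTRUE(all.equal(f1_score(cm), f1_score(flipped))))
})

test_that("goodness bands classify the quoted anchors", {
  expect_equal(as.character(goodness_category(0.08)), "optimum")
  expect_equal(as.character(goodness_category(0.25)), "optimum")
  expect_equal(as.character(goodness_category(0.46)), "good")
  expect_equal(as.character(goodness_category(sqrt(0.5))), "random")
  expect_equal(as.character(goodness_category(0.9)), "bad")
})

test_that("grouped 9-fold splits partition the cohort with sizes 4-5", {
  labels <- factor(rep(c("NR", "R"), c(26, 13)), levels = c("NR", "R"))
  folds <- split_folds(labels, "grouped-9fold", seed = 1)
  expect_length(folds, 9)
  sizes <- lengths(folds)
  expect_true(all(sizes %in% c(4, 5)))
  expect_equal(sort(unlist(folds)), 1:39)
  # pairwise disjoint by construction of the equality above
  # leave-one-out when n equals the fold count times one
  labels9 <- factor(rep(c("NR", "R"), c(6, 4)), levels = c("NR", "R"))
  folds9 <- split_folds(labels9, "grouped-9fold", n_folds = 9, seed = 1)
  expect_true(all(lengths(folds9) %in% c(1, 2)))
})

test_that("repeated-30-9 splits hold out 9 of 39 athletes per iteration", {
  labels <- factor(rep(c("NR", "R"), c(26, 13)), levels = c("NR", "R"))
  folds <- split_folds(labels, "repeated-30-9", seed = 2)
  expect_length(folds, 9)
  for (f in folds) {
    expect_length(f, 9)
    expect_length(unique(f), 9) # sampled without replacement
  }
})

test_that("all nine classifiers solve a perfectly separated toy problem", {
  toy <- toy_separable(20, sd = 0.1)
  b <- run_bench(toy$x, toy$y, seed = 1, n_folds = 5)
  expect_equal(nrow(b$metrics), 9)
  expect_true(all(b$metrics$accuracy == 1))
  expect_true(all(b$metrics$f1 == 1))
  expect_true(all(b$metrics$category == "optimum"))
  expect_equal(sum(b$metrics$tp + b$metrics$tn + b$metrics$fp +
                     b$metrics$fn), 9 * 40)
})

test_that("the bench is reproducible at the confusion-count level", {
  co <- sample_feature_cohort(20, 12, seed = 4)
  b1 <- run_bench(co$features, co$features$label, seed = 9)
  b2 <- run_bench(co$features, co$features$label, seed = 9)
  expect_identical(b1$metrics, b2$metrics)
})

test_that("test-fold statistics never leak into the scaler", {
  # corrupting one test athlete's features must not change the predictions
  # of other athletes in the same fold (train-only standardization)
  toy <- toy_separable(20, sd = 0.5, seed = 8)
  b0 <- run_bench(toy$x, toy$y, seed = 3, n_folds = 5)
  x2 <- toy$x
  victim <- b0$predictions$row[1]
  victim_fold <- b0$predictions$fold[1]
  x2$f1[victim] <- x2$f1[victim] * 1e6
  x2$f2[victim] <- -x2$f2[victim] * 1e6
  b1 <- run_bench(x2, toy$y, seed = 3, n_folds = 5)
  # the corrupted athlete sits in the training data of the other folds, so
  # only its own fold isolates the scaler question
  others <- b1$predictions$fold == victim_fold & b1$predictions$row != victim
  for (id in classifier_configs()$id) {
    expect_identical(b1$predictions[[id]][others],
                     b0$predictions[[id]][others])
  }
})

test_that("degenerate label inputs error", {
  toy <- toy_separable(5, seed = 2)
  expect_error(run_bench(toy$x, factor(rep("NR", 10), levels = c("NR", "R"))),
               "2 athletes per class")
  expect_error(run_bench(toy$x[1:5, ], toy$y), "mismatch")
})

test_that("kNN variants agree with the stock implementation where it exists", {
  toy <- toy_separable(15, sd = 3, seed = 6)
  x <- as.matrix(toy$x)
  train <- 1:20; test <- 21:30
  mine <- swayrisk:::knn_predict(x[train, ], toy$y[train], x[test, ],
                                 k = 1, distance = "euclidean",
                                 weight = "uniform")
  ref <- class::knn(x[train, ], x[test, ], toy$y[train], k = 1)
  expect_equal(as.character(mine), as.character(ref))
})

test_that("decision-tree split caps change model complexity", {
  # an XOR-like problem needs more than the 1-2 splits a tiny cap allows
  withr::with_seed(13, {
    x <- tibble::tibble(a = runif(200), b = runif(200))
  })
  y <- factor(ifelse(xor(x$a > 0.5, x$b > 0.5), "NR", "R"),
              levels = c("NR", "R"))
  p_coarse <- swayrisk:::fit_predict_tree(as.matrix(x[1:150, ]), y[1:150],
                                          as.matrix(x[151:200, ]), 1)
  p_complex <- swayrisk:::fit_predict_tree(as.matrix(x[1:150, ]), y[1:150],
                                           as.matrix(x[151:200, ]), 100)
  acc_coarse <- mean(p_coarse == y[151:200])
  acc_complex <- mean(p_complex == y[151:200])
  expect_gt(acc_complex, 0.9)
  expect_lt(acc_coarse, 0.8)
})
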