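#' The nine benchmark classifier configurations
#'
#' Three support vector machines with polynomial kernels of degree 1-3
#' (l-SVM, q-SVM, c-SVM), three k-nearest-neighbour variants (fine: k = 1
#' Euclidean; cosine: k = 10 cosine distance; weighted: k = 10 Euclidean
#' with squared-inverse-distance votes) and three Gini decision trees capped
#' at 4, 20 and 100 splits (coarse, medium, complex).
#'
#' @return tibble with columns `id`, `family`, `label` and a `params` list
#'   column.
#' @export
classifier_configs <- function() {
  tibble(
    id = c("l-SVM", "q-SVM", "c-SVM", "f-kNN", "c-kNN", "w-kNN",
           "c-DT", "m-DT", "cx-DT"),
    family = rep(c("SVM", "kNN", "DT"), each = 3),
    label = c("linear SVM", "quadratic SVM", "cubic SVM",
              "fine kNN", "cosine kNN", "weighted kNN",
              "coarse tree", "medium tree", "complex tree"),
    params = list(
      list(degree = 1), list(degree = 2), list(degree = 3),
      list(k = 1, distance = "euclidean", weight = "uniform"),
      list(k = 10, distance = "cosine", weight = "uniform"),
      list(k = 10, distance = "euclidean", weight = "squared_inverse"),
      list(max_splits = 4), list(max_splits = 20), list(max_splits = 100)
    )
  )
}

#' Cross-validation fold assignment
#'
#' Two interpretations of "9-fold cross-validation with 30 training and 9
#' validation athletes": `grouped-9fold` partitions the cohort into 9
#' disjoint, label-stratified test folds (sizes floor(n/9) or ceiling(n/9)),
#' so every athlete is tested exactly once; `repeated-30-9` runs 9
#' iterations, each holding out a fresh random 9-athlete validation set
#' (30 training when n = 39), so athletes may be tested more than once.
#'
#' @param labels factor of athlete labels (used for stratification and for
#'   `n`).
#' @param scheme `"grouped-9fold"` or `"repeated-30-9"`.
#' @param n_folds number of folds / iterations.
#' @param seed integer seed.
#' @return list of integer index vectors, the test sets.
#' @export
split_folds <- function(labels, scheme = c("grouped-9fold", "repeated-30-9"),
                        n_folds = 9, seed = 1) {
  scheme <- match.arg(scheme)
  n <- length(labels)
  if (n < n_folds + 1) abort_swayrisk("need more athletes than folds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (scheme == "grouped-9fold") {
    # stratified round-robin so each training fold sees both classes
    fold_of <- integer(n)
    offset <- 0
    for (lv in levels(factor(labels))) {
      idx <- sample(which(labels == lv))
      fold_of[idx] <- (seq_along(idx) - 1 + offset) %% n_folds + 1
      offset <- offset + length(idx)
    }
    lapply(seq_len(n_folds), function(f) which(fold_of == f))
  } else {
    lapply(seq_len(n_folds), function(f) sort(sample(n, 9)))
  }
}

# ---- individual learners -----------------------------------------------------

fit_predict_svm <- function(x_train, y_train, x_test, degree) {
  kern <- if (degree == 1) "linear" else "polynomial"
  fit <- e1071::svm(x_train, y_train, kernel = kern, degree = degree,
                    coef0 = if (degree > 1) 1 else 0, cost = 1,
                    scale = FALSE)
  stats::predict(fit, x_test)
}

# kNN with the benchmark's distance/vote variants (cosine distance and
# squared-inverse weighting are not offered by the stock kNN
# implementations)
knn_predict <- function(x_train, y_train, x_test, k, distance = "euclidean",
                        weight = "uniform") {
  y_train <- factor(y_train)
  d <- if (distance == "cosine") {
    ntr <- sqrt(rowSums(x_train^2)); nte <- sqrt(rowSums(x_test^2))
    ntr[ntr == 0] <- 1e-12; nte[nte == 0] <- 1e-12
    1 - (x_test %*% t(x_train)) / outer(nte, ntr)
  } else {
    xt2 <- rowSums(x_train^2); xe2 <- rowSums(x_test^2)
    d2 <- outer(xe2, xt2, "+") - 2 * x_test %*% t(x_train)
    sqrt(pmax(d2, 0))
  }
  k <- min(k, nrow(x_train))
  lv <- levels(y_train)
  pred <- character(nrow(x_test))
  for (i in seq_len(nrow(x_test))) {
    ord <- order(d[i, ])[seq_len(k)]
    wts <- switch(weight,
      uniform = rep(1, k),
      squared_inverse = 1 / pmax(d[i, ord], 1e-12)^2
    )
    votes <- tapply(wts, y_train[ord], sum, default = 0)
    pred[i] <- lv[which.max(votes[lv])]
  }
  factor(pred, levels = lv)
}

fit_predict_tree <- function(x_train, y_train, x_test, max_splits) {
  df <- as.data.frame(x_train); df$.y <- y_train
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                        maxsurrogate = 0))
  # cap the number of internal splits by pruning back along the cp path
  cpt <- fit$cptable
  ok <- cpt[, "nsplit"] <= max_splits
  if (any(ok)) {
    target <- max(cpt[ok, "nsplit"])
    cp_prune <- cpt[cpt[, "nsplit"] == target, "CP"][1]
    fit <- rpart::prune(fit, cp = cp_prune)
  }
  stats::predict(fit, as.data.frame(x_test), type = "class")
}

fit_predict_config <- function(config_params, family, x_train, y_train,
                               x_test) {
  switch(family,
    SVM = fit_predict_svm(x_train, y_train, x_test, config_params$degree),
    kNN = knn_predict(x_train, y_train, x_test, config_params$k,
                      config_params$distance, config_params$weight),
    DT = fit_predict_tree(x_train, y_train, x_test, config_params$max_splits)
  )
}

# ---- metrics -----------------------------------------------------------------

#' Confusion matrix with the no-risk class as positive
#'
#' @param truth,estimate factors with levels `NR`, `R`; `NR` is the positive
#'   class.
#' @return tibble with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, estimate) {
  truth <- factor(truth, levels = c("NR", "R"))
  estimate <- factor(estimate, levels = c("NR", "R"))
  tibble(
    tp = sum(truth == "NR" & estimate == "NR"),
    tn = sum(truth == "R" & estimate == "R"),
    fp = sum(truth == "R" & estimate == "NR"),
    fn = sum(truth == "NR" & estimate == "R")
  )
}

#' Classifier performance metrics
#'
#' `accuracy()` is the fraction of correct predictions,
#' `(TP + TN) / (TP + TN + FP + FN)`. `f1_score()` is the harmonic mean of
#' recall `TP / (TP + FN)` and precision `TP / (TP + FP)` for the
#' NR-positive convention (0 when TP = 0). `g_index()` is the Euclidean
#' distance in ROC space between the classifier and the perfect one,
#' `sqrt((1 - sensitivity)^2 + (1 - specificity)^2)`, ranging 0 (perfect) to
#' `sqrt(2)` (always wrong); the chance classifier sits at `sqrt(0.5)`,
#' commonly quoted as 0.70.
#'
#' @param cm a one-row tibble/list with `tp`, `tn`, `fp`, `fn`.
#' @return a single number.
#' @export
#' @examples
#' cm <- tibble::tibble(tp = 20, tn = 10, fp = 6, fn = 3)
#' accuracy(cm); f1_score(cm); g_index(cm)
accuracy <- function(cm) {
  (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn)
}

#' @rdname accuracy
#' @export
f1_score <- function(cm) {
  if (cm$tp == 0) return(0)
  re <- cm$tp / (cm$tp + cm$fn)
  pr <- cm$tp / (cm$tp + cm$fp)
  2 * re * pr / (re + pr)
}

#' @rdname accuracy
#' @export
g_index <- function(cm) {
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) {
    abort_swayrisk("g_index needs both classes present")
  }
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  sqrt((1 - sens)^2 + (1 - spec)^2)
}

#' Goodness category of a G index
#'
#' Bands: optimum when `G <= 0.25`; good when `0.25 < G < sqrt(0.5)`; random
#' at the chance-classifier distance `G = sqrt(0.5)` (quoted as 0.70); bad
#' beyond it.
#'
#' @param g a G index in `[0, sqrt(2)]`.
#' @return factor level among `optimum`, `good`, `random`, `bad`.
#' @export
goodness_category <- function(g) {
  lv <- c("optimum", "good", "random", "bad")
  out <- ifelse(g <= 0.25, "optimum",
         ifelse(abs(g - sqrt(0.5)) < 1e-9, "random",
         ifelse(g < sqrt(0.5), "good", "bad")))
  factor(out, levels = lv)
}

#' Run the nine-classifier cross-validated benchmark
#'
#' For each fold, features are standardized to zero mean / unit SD using
#' training-fold statistics only (distance-based learners are meaningless
#' across features spanning square centimetres to hundreds of m/s^2);
#' each configured classifier is fitted on the training fold and its test
#' predictions collected. Confusion counts are pooled (summed) across folds
#' and accuracy, F1 and the goodness index computed on the pooled matrix;
#' per-fold averaging of the metrics is available as an option.
#'
#' @param features data frame / tibble of numeric feature columns (extra
#'   non-numeric columns such as ids are dropped), one row per athlete.
#' @param labels factor (`NR`/`R`) of reference labels, NR positive.
#' @param configs classifier configuration tibble, by default all nine from
#'   [classifier_configs()].
#' @param scheme CV scheme, see [split_folds()].
#' @param n_folds number of folds.
#' @param seed integer seed (fold assignment).
#' @param fold_average also report per-fold averaged accuracy.
#' @return object of class `sway_bench`: list with `metrics` (tibble: one
#'   row per classifier with confusion counts, `accuracy`, `f1`, `g`,
#'   `category`), `predictions` (per-athlete test predictions, one column
#'   per classifier), `scheme`, `seed`.
#' @export
run_bench <- function(features, labels,
                      configs = classifier_configs(),
                      scheme = c("grouped-9fold", "repeated-30-9"),
                      n_folds = 9, seed = 1, fold_average = FALSE) {
  scheme <- match.arg(scheme)
  labels <- factor(labels, levels = c("NR", "R"))
  x <- as.data.frame(features)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) abort_swayrisk("features/labels mismatch")
  if (any(!stats::complete.cases(x))) abort_swayrisk("missing feature values")
  if (min(table(labels)) < 2) {
    abort_swayrisk("need at least 2 athletes per class")
  }
  folds <- split_folds(labels, scheme, n_folds, seed)

  preds <- vector("list", nrow(configs))
  names(preds) <- configs$id
  truth_all <- list()
  fold_acc <- matrix(NA_real_, length(folds), nrow(configs),
                     dimnames = list(NULL, configs$id))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    y_train <- labels[train_idx]
    if (length(unique(y_train)) < 2) {
      abort_swayrisk(
        "a training fold contains a single class: use stratified folds",
        class = "swayrisk_fold_error")
    }
    mu <- colMeans(x[train_idx, , drop = FALSE])
    sg <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    x_train <- sweep(sweep(x[train_idx, , drop = FALSE], 2, mu), 2, sg, "/")
    x_test <- sweep(sweep(x[test_idx, , drop = FALSE], 2, mu), 2, sg, "/")
    truth_all[[f]] <- labels[test_idx]
    for (ci in seq_len(nrow(configs))) {
      p <- fit_predict_config(configs$params[[ci]], configs$family[ci],
                              x_train, y_train, x_test)
      preds[[configs$id[ci]]][[f]] <- factor(as.character(p),
                                             levels = c("NR", "R"))
      fold_acc[f, ci] <- mean(p == labels[test_idx])
    }
  }
  truth <- factor(unlist(lapply(truth_all, as.character)),
                  levels = c("NR", "R"))
  predictions <- tibble(
    row = unlist(folds),
    fold = rep(seq_along(folds), lengths(folds)),
    truth = truth
  )
  for (id in configs$id) {
    predictions[[id]] <- factor(unlist(lapply(preds[[id]], as.character)),
                                levels = c("NR", "R"))
  }
  metrics <- purrr::imap(preds, function(pl, id) {
    est <- factor(unlist(lapply(pl, as.character)), levels = c("NR", "R"))
    cm <- confusion_counts(truth, est)
    dplyr::mutate(cm, id = id, .before = 1,
                  accuracy = accuracy(cm), f1 = f1_score(cm),
                  g = g_index(cm), category = goodness_category(g_index(cm)))
  }) |> purrr::list_rbind()
  metrics <- dplyr::left_join(configs[, c("id", "family", "label")],
                              metrics, by = "id")
  if (fold_average) {
    metrics$fold_mean_accuracy <- colMeans(fold_acc)[metrics$id]
  }
  structure(list(metrics = as_tibble(metrics), predictions = predictions,
                 scheme = scheme, seed = seed, n = nrow(x)),
            class = "sway_bench")
}

#' @export
print.sway_bench <- function(x, ...) {
  cat(sprintf("<sway_bench> %s, n = %d, seed = %d\n", x$scheme, x$n, x$seed))
  print(as.data.frame(dplyr::select(
    x$metrics, "id", "tp", "tn", "fp", "fn", "accuracy", "f1", "g",
    "category")), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidiers for benchmark results
#'
#' `tidy()` returns the per-classifier metric table; `glance()` a one-row
#' summary with the best classifier by goodness index.
#'
#' @param x a `sway_bench`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.sway_bench <- function(x, ...) x$metrics

#' @rdname tidy.sway_bench
#' @export
glance.sway_bench <- function(x, ...) {
  best <- x$metrics[which.min(x$metrics$g), ]
  tibble(
    n = x$n, scheme = x$scheme, n_classifiers = nrow(x$metrics),
    n_optimum = sum(x$metrics$category == "optimum"),
    best_id = best$id, best_accuracy = best$accuracy, best_f1 = best$f1,
    best_g = best$g
  )
}

#' Plot benchmark metrics
#'
#' Bar chart of accuracy, F1 and goodness index per classifier, with the
#' optimum-band thresholds marked.
#'
#' @param object a `sway_bench`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sway_bench <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("accuracy", "f1", "g"),
                              names_to = "metric", values_to = "value")
  thr <- tibble(metric = c("accuracy", "f1", "g"),
                threshold = c(0.8, 0.8, 0.25))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Classifier benchmark (pooled cross-validation)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
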