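#' Random-forest out-of-bag permutation importance (mean decrease accuracy)
#'
#' A random forest is grown with bootstrap bookkeeping; for every feature,
#' its values are permuted (seeded) and each tree is re-evaluated on its
#' out-of-bag rows. The mean decrease accuracy is the per-tree drop in OOB
#' accuracy caused by the permutation, averaged across trees and expressed
#' in percentage points. Features the labels do not depend on converge to 0;
#' the more a classifier leans on a feature, the larger its MDA.
#'
#' @param features data frame of numeric feature columns (non-numeric
#'   columns dropped), one row per athlete.
#' @param labels factor of class labels.
#' @param n_trees number of trees (>= 50).
#' @param seed integer seed (forest growth and permutations).
#' @param n_repeats number of independent permutations per feature, averaged
#'   to reduce the estimator variance.
#' @param threshold importance threshold (percentage points) used by the
#'   plot method to mark "important" features.
#' @return object of class `sway_importance`: list with `importance`
#'   (tibble: `feature`, `mda`, `rank`), `n_trees`, `threshold`, `seed`.
#' @export
mda_importance <- function(features, labels, n_trees = 500, seed = 1,
                           n_repeats = 1, threshold = 15.0) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) abort_swayrisk("need >= 2 classes")
  if (n_trees < 50) abort_swayrisk("n_trees must be >= 50")
  x <- as.data.frame(features)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  zero_var <- vapply(x, function(col) stats::sd(col) == 0, logical(1))
  if (any(zero_var)) {
    warning("zero-variance feature(s): MDA defined as 0 for ",
            paste(names(x)[zero_var], collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = n_trees,
                                   keep.inbag = TRUE, keep.forest = TRUE)
  inbag <- rf$inbag # n x ntree counts
  base_pred <- stats::predict(rf, x, predict.all = TRUE)$individual
  y_chr <- as.character(labels)
  oob <- inbag == 0
  n_oob <- colSums(oob)
  keep_tree <- n_oob > 0
  base_acc <- vapply(seq_len(n_trees), function(t) {
    if (!keep_tree[t]) return(NA_real_)
    mean(base_pred[oob[, t], t] == y_chr[oob[, t]])
  }, numeric(1))

  mda <- numeric(p)
  for (j in seq_len(p)) {
    if (zero_var[j]) { mda[j] <- 0; next }
    drops <- matrix(NA_real_, sum(keep_tree), n_repeats)
    for (r in seq_len(n_repeats)) {
      xp <- x
      xp[[j]] <- x[[j]][sample.int(n)]
      perm_pred <- stats::predict(rf, xp, predict.all = TRUE)$individual
      ti <- 0
      for (t in which(keep_tree)) {
        ti <- ti + 1
        o <- oob[, t]
        drops[ti, r] <- base_acc[t] - mean(perm_pred[o, t] == y_chr[o])
      }
    }
    mda[j] <- mean(drops) * 100
  }
  imp <- tibble(feature = names(x), mda = mda) |>
    dplyr::mutate(rank = rank(-.data$mda, ties.method = "first"))
  structure(list(importance = imp, n_trees = n_trees, threshold = threshold,
                 seed = seed, rf = rf),
            class = "sway_importance")
}

#' @export
print.sway_importance <- function(x, ...) {
  cat(sprintf("<sway_importance> %d trees, threshold %.1f%%\n",
              x$n_trees, x$threshold))
  print(as.data.frame(dplyr::arrange(x$importance, .data$rank)),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.sway_bench
#' @export
tidy.sway_importance <- function(x, ...) x$importance

#' Bar chart of permutation importances
#'
#' Mirrors the usual importance histogram with a dashed line at the
#' importance threshold.
#'
#' @param object a `sway_importance`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sway_importance <- function(object, ...) {
  imp <- dplyr::arrange(object$importance, .data$mda)
  imp$feature <- factor(imp$feature, levels = imp$feature)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$feature, y = .data$mda)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "red") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean decrease accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Spearman correlation with interpretation band
#'
#' Rank correlation (mid-ranks for ties) with the large-sample p-value, and
#' the interpretation band: none (|r| <= 0.1), mild/modest (0.1 < |r| <=
#' 0.3), moderate (0.3 < |r| <= 0.6), strong (0.6 < |r| < 1) and perfect
#' (|r| = 1); boundary values fall in the lower-|r| band.
#'
#' @param x,y paired numeric vectors (>= 5 observations).
#' @return tibble with `r`, `p_value`, `band`.
#' @export
spearman_band <- function(x, y) {
  if (length(x) != length(y) || length(x) < 5) {
    abort_swayrisk("need >= 5 paired observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_swayrisk("constant input: rank correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  r <- unname(ct$estimate)
  band <- if (abs(abs(r) - 1) < 1e-12) "perfect"
    else if (abs(r) <= 0.1) "none"
    else if (abs(r) <= 0.3) "mild/modest"
    else if (abs(r) <= 0.6) "moderate"
    else "strong"
  tibble(r = r, p_value = ct$p.value,
         band = factor(band, levels = c("none", "mild/modest", "moderate",
                                        "strong", "perfect")))
}
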