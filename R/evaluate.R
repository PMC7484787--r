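#' Repeated random-split evaluation of the decision-tree classifier
#'
#' The published protocol: for each repeat a fresh uniform (unstratified)
#' 60/40 train/test split is drawn, a Gini CART (depth 6, min split 2,
#' equal weights) is grown on the training portion, and the test
#' confusion matrix yields per-class sensitivity (true positive rate)
#' and specificity (true negative rate), one-vs-rest in the three-class
#' scheme. Rates are reported as mean +/- SD across repeats; a repeat
#' whose test set lacks a class contributes no rate for that class (the
#' skip is counted). ROC points are built from leaf class probabilities
#' pooled across repeats.
#'
#' @param cohort data.frame from [generate_cohort()], or a list
#'   `(X, y)` with a precomputed feature matrix and labels.
#' @param scheme `"binary"` (0 mast cell, 1 other) or `"three_class"`
#'   (0 activated MC, 1 resting MC, 2 other).
#' @param n_repeats number of randomized splits (default 1000).
#' @param test_fraction held-out fraction (default 0.4).
#' @param base_seed integer; repeat `r` uses seed `base_seed + r`.
#' @param max_depth,min_samples_split tree hyperparameters.
#' @return a `classifier_report`: list with `per_class` (data.frame of
#'   mean/SD sensitivity and specificity and skip counts), `confusion`
#'   (summed over repeats), `roc` (pooled one-vs-rest curves), and the
#'   evaluation settings.
#' @export
evaluate <- function(cohort, scheme = c("binary", "three_class"),
                     n_repeats = 1000, test_fraction = 0.4,
                     base_seed = 1, max_depth = 6, min_samples_split = 2) {
  scheme <- match.arg(scheme)
  if (is.data.frame(cohort)) {
    X <- cohort_features(cohort)
    y <- if (scheme == "binary") cohort$label_binary else cohort$label_three
  } else {
    X <- cohort$X
    y <- cohort$y
  }
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) stop("evaluation needs at least two classes")
  n <- nrow(X)
  n_test <- round(test_fraction * n)

  sens <- matrix(NA_real_, n_repeats, K)
  spec <- matrix(NA_real_, n_repeats, K)
  confusion <- matrix(0, K, K, dimnames = list(truth = classes,
                                               predicted = classes))
  pooled_prob <- vector("list", n_repeats)
  pooled_truth <- vector("list", n_repeats)

  for (r in seq_len(n_repeats)) {
    set.seed(base_seed + r)
    test_idx <- sample.int(n, n_test)
    train_idx <- setdiff(seq_len(n), test_idx)
    tree <- grow_tree(X[train_idx, , drop = FALSE], y[train_idx],
                      max_depth = max_depth,
                      min_samples_split = min_samples_split)
    pred <- predict_tree(tree, X[test_idx, , drop = FALSE])
    truth <- y[test_idx]
    # tree may not have seen every class; expand probabilities to all K
    prob <- matrix(0, length(test_idx), K,
                   dimnames = list(NULL, as.character(classes)))
    prob[, as.character(tree$classes)] <- pred$prob
    cm <- table(factor(truth, levels = classes),
                factor(pred$class, levels = classes))
    confusion <- confusion + cm
    for (k in seq_len(K)) {
      pos <- truth == classes[k]
      if (any(pos)) sens[r, k] <- mean(pred$class[pos] == classes[k])
      if (any(!pos)) spec[r, k] <- mean(pred$class[!pos] != classes[k])
    }
    pooled_prob[[r]] <- prob
    pooled_truth[[r]] <- truth
  }

  prob_all <- do.call(rbind, pooled_prob)
  truth_all <- unlist(pooled_truth)
  roc <- do.call(rbind, lapply(seq_len(K), function(k) {
    roc_points(prob_all[, k], truth_all == classes[k], classes[k])
  }))
  per_class <- data.frame(
    class = classes,
    sensitivity_mean = colMeans(sens, na.rm = TRUE),
    sensitivity_sd = apply(sens, 2, stats::sd, na.rm = TRUE),
    specificity_mean = colMeans(spec, na.rm = TRUE),
    specificity_sd = apply(spec, 2, stats::sd, na.rm = TRUE),
    skipped = colSums(is.na(sens)))
  structure(list(per_class = per_class, confusion = confusion, roc = roc,
                 scheme = scheme, n_repeats = n_repeats,
                 test_fraction = test_fraction, base_seed = base_seed,
                 n = n),
            class = "classifier_report")
}

# one-vs-rest ROC curve from pooled scores
roc_points <- function(score, positive, class_label) {
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(score[positive] >= t), 0)
  fpr <- vapply(th, function(t) mean(score[!positive] >= t), 0)
  data.frame(class = class_label,
             threshold = c(Inf, th), tpr = c(0, tpr), fpr = c(0, fpr))
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Decision-tree evaluation (%s, %d repeats, %.0f%% test)\n",
              x$scheme, x$n_repeats, 100 * x$test_fraction))
  df <- x$per_class
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  class %s: sensitivity %.2f +/- %.2f, specificity %.2f +/- %.2f\n",
                df$class[i], df$sensitivity_mean[i], df$sensitivity_sd[i],
                df$specificity_mean[i], df$specificity_sd[i]))
  }
  invisible(x)
}
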