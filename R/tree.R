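#' Gini impurity of a label set
#'
#' `1 - sum_k p_k^2` over the class proportions of the node; 0 for a
#' pure node, at most `1 - 1/K` for `K` balanced classes.
#'
#' @param labels vector of class labels (any atomic type).
#' @export
gini <- function(labels) {
  if (length(labels) == 0) stop("Gini impurity undefined for an empty node")
  p <- tabulate(match(labels, unique(labels))) / length(labels)
  1 - sum(p^2)
}

#' Best axis-aligned split of a node
#'
#' Exhaustive search over every feature and every midpoint between
#' consecutive distinct sorted values, minimizing the weighted child
#' Gini impurity `G = (n_L H_L + n_R H_R) / N` with the inclusive-left
#' partition `x_j <= t`. Ties are broken toward the lowest feature
#' index, then the lowest threshold.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y class labels.
#' @param rows optional subset of row indices forming the node.
#' @return list `(feature, threshold, score)`, or `NULL` when every
#'   sample is identical in every feature (leaf signal).
#' @export
best_split <- function(X, y, rows = seq_len(nrow(X))) {
  classes <- sort(unique(y))
  yk <- match(y, classes) - 1L
  res <- .cart_best_split(X, yk, as.integer(rows - 1L), length(classes))
  if (res$feature == 0) return(NULL)
  res
}

#' Grow a CART decision tree
#'
#' Recursive binary splitting with Gini impurity: a node is split while
#' it holds at least `min_samples_split` samples, is impure, sits above
#' `max_depth`, and a valid split exists; leaves store the class
#' proportion table `p_mk = (1/N_m) * sum I(y_i = k)`. All samples carry
#' equal weight. Defaults match the published protocol: Gini criterion,
#' minimum samples to split 2, maximum depth 6.
#'
#' @param X numeric feature matrix.
#' @param y class labels (coerced to their sorted unique levels).
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_samples_split minimum node size eligible for splitting.
#' @return a `cart_tree` object.
#' @export
grow_tree <- function(X, y, max_depth = 6, min_samples_split = 2) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  classes <- sort(unique(y))
  yk <- match(y, classes)
  grow <- function(rows, depth) {
    p <- tabulate(yk[rows], nbins = length(classes)) / length(rows)
    node <- list(n = length(rows), prob = p)
    if (length(rows) >= min_samples_split && depth < max_depth &&
        gini(yk[rows]) > 0) {
      sp <- best_split(X, y, rows)
      if (!is.null(sp)) {
        left <- rows[X[rows, sp$feature] <= sp$threshold]
        right <- setdiff(rows, left)
        node$feature <- sp$feature
        node$threshold <- sp$threshold
        node$left <- grow(left, depth + 1)
        node$right <- grow(right, depth + 1)
      }
    }
    node
  }
  structure(list(root = grow(seq_len(nrow(X)), 0), classes = classes,
                 n_features = ncol(X), max_depth = max_depth,
                 min_samples_split = min_samples_split),
            class = "cart_tree")
}

#' Predict with a CART tree
#'
#' Routes each sample by `x_j <= t` (boundary points go left) to a leaf
#' and returns the argmax class (ties toward the lowest class index)
#' plus the leaf's full class-proportion row.
#'
#' @param tree a `cart_tree`.
#' @param X numeric matrix (or vector for a single sample).
#' @return list with `class` (vector) and `prob` (matrix, one row per
#'   sample, columns named by class).
#' @export
predict_tree <- function(tree, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != tree$n_features) stop("feature dimension mismatch")
  if (any(!is.finite(X))) stop("non-finite feature value")
  probs <- matrix(NA_real_, nrow(X), length(tree$classes))
  colnames(probs) <- as.character(tree$classes)
  for (i in seq_len(nrow(X))) {
    node <- tree$root
    while (!is.null(node$feature)) {
      node <- if (X[i, node$feature] <= node$threshold) node$left else
        node$right
    }
    probs[i, ] <- node$prob
  }
  list(class = tree$classes[max.col(probs, ties.method = "first")],
       prob = probs)
}

#' Tree depth
#' @param tree a `cart_tree`.
#' @export
tree_depth <- function(tree) {
  depth <- function(node) {
    if (is.null(node$feature)) return(0L)
    1L + max(depth(node$left), depth(node$right))
  }
  depth(tree$root)
}
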