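# Compact random forest (bagged CART with gini splits and random feature
# subsets). No random-forest package ships with this R installation; this
# stays behind the rf_baseline surface.

#' @noRd
gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best gini split of one feature column: scan sorted midpoints via prefix
# class counts. Returns list(gain, threshold) or NULL.
#' @noRd
best_split_feature <- function(x, y, K) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  counts <- matrix(0L, n, K)
  counts[cbind(seq_len(n), ys)] <- 1L
  left <- apply(counts, 2, cumsum)
  total <- left[n, ]
  parent <- gini_impurity(total)
  cut_ok <- which(diff(xs) > 1e-12)
  if (length(cut_ok) == 0L) return(NULL)
  nl <- cut_ok
  nr <- n - nl
  gl <- 1 - rowSums((left[cut_ok, , drop = FALSE] / nl)^2)
  right <- matrix(total, length(cut_ok), K, byrow = TRUE) -
    left[cut_ok, , drop = FALSE]
  gr <- 1 - rowSums((right / nr)^2)
  gain <- parent - (nl * gl + nr * gr) / n
  i <- which.max(gain)
  if (gain[i] <= 1e-12) return(NULL)
  list(gain = gain[i], threshold = (xs[cut_ok[i]] + xs[cut_ok[i] + 1L]) / 2)
}

#' @noRd
grow_tree <- function(X, y, K, mtry, max_depth, min_node, depth = 0L) {
  counts <- tabulate(y, K)
  if (depth >= max_depth || length(y) < min_node ||
      gini_impurity(counts) < 1e-12) {
    return(list(leaf = TRUE, class = which.max(counts)))
  }
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- NULL; best_f <- NA_integer_
  for (f in feats) {
    sp <- best_split_feature(X[, f], y, K)
    if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
      best <- sp; best_f <- f
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, class = which.max(counts)))
  go_left <- X[, best_f] <= best$threshold
  list(leaf = FALSE, feature = best_f, threshold = best$threshold,
       left = grow_tree(X[go_left, , drop = FALSE], y[go_left], K, mtry,
                        max_depth, min_node, depth + 1L),
       right = grow_tree(X[!go_left, , drop = FALSE], y[!go_left], K, mtry,
                         max_depth, min_node, depth + 1L))
}

#' @noRd
predict_tree <- function(tree, X) {
  out <- integer(nrow(X))
  walk <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    gl <- X[idx, node$feature] <= node$threshold
    walk(node$left, idx[gl])
    walk(node$right, idx[!gl])
  }
  walk(tree, seq_len(nrow(X)))
  out
}

#' @noRd
fit_forest <- function(X, y, K, n_trees = 100L, max_depth = 12L,
                       min_node = 2L, mtry = NULL) {
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    bag <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(X[bag, , drop = FALSE], y[bag], K, mtry,
                            max_depth, min_node)
  }
  list(trees = trees, K = K)
}

#' @noRd
predict_forest <- function(forest, X) {
  votes <- matrix(0L, nrow(X), forest$K)
  for (tree in forest$trees) {
    pred <- predict_tree(tree, X)
    votes[cbind(seq_len(nrow(X)), pred)] <- votes[cbind(seq_len(nrow(X)),
                                                        pred)] + 1L
  }
  max.col(votes, ties.method = "first")
}
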