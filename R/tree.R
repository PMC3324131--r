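# Recursive-partitioning regression tree shared by the CART learner and
# the random forest. Splits are axis-aligned thresholds; on the 0/1
# genotype columns the only candidate is x < 0.5. A split is kept when
# it reduces the training RSS by at least cp * RSS(root) and respects
# the minimum node sizes.

# Best split of y[idx] on one column. Returns NULL or
# list(threshold, delta = RSS reduction).
best_split_one <- function(x, y, min_bucket) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(ys)
  # candidate cut after position i: xs[i] < xs[i + 1]
  cuts <- which(xs[-n] < xs[-1])
  cuts <- cuts[cuts >= min_bucket & (n - cuts) >= min_bucket]
  if (!length(cuts)) return(NULL)
  csum <- cumsum(ys)
  tot <- csum[n]
  # RSS reduction = n_l n_r / n * (mean_l - mean_r)^2 rearranged:
  delta <- csum[cuts]^2 / cuts + (tot - csum[cuts])^2 / (n - cuts) - tot^2 / n
  b <- which.max(delta)
  list(threshold = (xs[cuts[b]] + xs[cuts[b] + 1]) / 2, delta = delta[b])
}

grow_tree <- function(X, y, mtry = ncol(X), min_split = 10L, min_bucket = 5L,
                      cp = 0.01, idx = seq_along(y),
                      root_rss = sum((y - mean(y))^2)) {
  node_y <- y[idx]
  value <- mean(node_y)
  if (length(idx) < min_split || stats::var(node_y) == 0) {
    return(list(leaf = TRUE, value = value, n = length(idx)))
  }
  vars <- if (mtry >= ncol(X)) seq_len(ncol(X)) else
    sample.int(ncol(X), mtry)
  best <- NULL
  for (v in vars) {
    s <- best_split_one(X[idx, v], node_y, min_bucket)
    if (!is.null(s) && (is.null(best) || s$delta > best$delta)) {
      best <- c(s, var = v)
    }
  }
  # cp rule relative to the root node's RSS, as in cost-complexity pruning
  if (is.null(best) || best$delta < cp * root_rss - 1e-12) {
    return(list(leaf = TRUE, value = value, n = length(idx)))
  }
  go_left <- X[idx, best$var] < best$threshold
  list(leaf = FALSE, var = best$var, threshold = best$threshold,
       value = value, n = length(idx),
       left = grow_tree(X, y, mtry, min_split, min_bucket, cp,
                        idx[go_left], root_rss),
       right = grow_tree(X, y, mtry, min_split, min_bucket, cp,
                         idx[!go_left], root_rss))
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) {
      out[rows] <<- node$value
      return()
    }
    go_left <- X[rows, node$var] < node$threshold
    rec(node$left, rows[go_left])
    rec(node$right, rows[!go_left])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

tree_vars <- function(tree) {
  if (tree$leaf) return(integer(0))
  sort(unique(c(tree$var, tree_vars(tree$left), tree_vars(tree$right))))
}

tree_n_leaves <- function(tree) {
  if (tree$leaf) return(1L)
  tree_n_leaves(tree$left) + tree_n_leaves(tree$right)
}
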