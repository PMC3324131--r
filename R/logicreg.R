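# Logic regression: y ~ b0 + b1 * L(X) with L a single Boolean tree
# over the mutation indicators, searched by simulated annealing over
# the move set {alternate leaf, alternate operator, grow branch, prune
# branch, split leaf}, with (b0, b1) refit in closed form at every
# state. Tree size is chosen by internal cross-validation (1-SE rule)
# over leaf budgets 0..max_leaves; budget 0 is the intercept-only model.

# Closed-form OLS of y on a single 0/1 column.
logic_objective <- function(y, L) {
  n <- length(y)
  sy <- sum(y)
  syy <- sum(y * y)
  sL <- sum(L)
  if (sL == 0 || sL == n) {
    b0 <- sy / n
    return(list(rss = syy - sy * b0, b0 = b0, b1 = 0, degenerate = TRUE))
  }
  sLy <- sum(y * L)
  b1 <- (sLy - sL * sy / n) / (sL - sL * sL / n)
  b0 <- (sy - b1 * sL) / n
  rss <- syy - 2 * b0 * sy - 2 * b1 * sLy + b0 * b0 * n +
    2 * b0 * b1 * sL + b1 * b1 * sL
  list(rss = max(rss, 0), b0 = b0, b1 = b1, degenerate = FALSE)
}

# Node addressing: a path is an integer vector of 1 (left) / 2 (right);
# the root is the empty path.
btree_paths <- function(tree, kind = c("any", "leaf", "op")) {
  kind <- match.arg(kind)
  acc <- list()
  rec <- function(node, path) {
    keep <- switch(kind, any = TRUE,
                   leaf = node$type == "leaf",
                   op = node$type == "op")
    if (keep) acc[[length(acc) + 1L]] <<- path
    if (node$type == "op") {
      rec(node$l, c(path, 1L))
      rec(node$r, c(path, 2L))
    }
  }
  rec(tree, integer(0))
  acc
}

btree_get <- function(tree, path) {
  for (step in path) tree <- if (step == 1L) tree$l else tree$r
  tree
}

btree_set <- function(tree, path, new) {
  if (!length(path)) return(new)
  if (path[1] == 1L) {
    tree$l <- btree_set(tree$l, path[-1], new)
  } else {
    tree$r <- btree_set(tree$r, path[-1], new)
  }
  tree
}

# Bare-list node constructors for the hot annealing loop; the final
# tree is promoted to a classed btree for the user.
bare_leaf <- function(p) {
  list(type = "leaf", var = sample.int(p, 1L), neg = stats::runif(1) < 0.5)
}

bare_op <- function(l, r) {
  list(type = "op", op = if (stats::runif(1) < 0.5) "and" else "or",
       l = l, r = r)
}

classify_btree <- function(tree) {
  if (is.null(tree)) return(NULL)
  if (tree$type == "op") {
    tree$l <- classify_btree(tree$l)
    tree$r <- classify_btree(tree$r)
  }
  structure(tree, class = "btree")
}

# One random move from the logic-regression move set, respecting the
# leaf budget. Returns list(tree, n_leaves).
propose_btree_move <- function(tree, n_leaves, p, max_leaves) {
  moves <- c("alternate_leaf",
             if (n_leaves > 1L) c("alternate_operator", "prune_branch"),
             if (n_leaves < max_leaves) c("grow_branch", "split_leaf"))
  move <- moves[sample.int(length(moves), 1L)]
  if (move == "alternate_leaf") {
    paths <- btree_paths(tree, "leaf")
    path <- paths[[sample.int(length(paths), 1L)]]
    return(list(tree = btree_set(tree, path, bare_leaf(p)),
                n_leaves = n_leaves))
  }
  if (move == "alternate_operator") {
    paths <- btree_paths(tree, "op")
    path <- paths[[sample.int(length(paths), 1L)]]
    node <- btree_get(tree, path)
    node$op <- if (node$op == "and") "or" else "and"
    return(list(tree = btree_set(tree, path, node), n_leaves = n_leaves))
  }
  if (move == "grow_branch") {
    # wrap a random (sub)tree in a new operator with a fresh leaf
    paths <- btree_paths(tree, "any")
    path <- paths[[sample.int(length(paths), 1L)]]
    node <- btree_get(tree, path)
    return(list(tree = btree_set(tree, path, bare_op(node, bare_leaf(p))),
                n_leaves = n_leaves + 1L))
  }
  if (move == "split_leaf") {
    paths <- btree_paths(tree, "leaf")
    path <- paths[[sample.int(length(paths), 1L)]]
    node <- btree_get(tree, path)
    return(list(tree = btree_set(tree, path, bare_op(node, bare_leaf(p))),
                n_leaves = n_leaves + 1L))
  }
  # prune_branch: replace an operator node by one of its children
  paths <- btree_paths(tree, "op")
  path <- paths[[sample.int(length(paths), 1L)]]
  node <- btree_get(tree, path)
  keep <- if (stats::runif(1) < 0.5) node$l else node$r
  new_tree <- btree_set(tree, path, keep)
  list(tree = new_tree, n_leaves = btree_n_leaves(new_tree))
}

# Simulated annealing at a fixed leaf budget. Geometric cooling; the
# start temperature is set from a pilot so roughly half of the uphill
# moves are accepted, and the end temperature makes final acceptance
# essentially zero. Best-visited state is kept. Caller seeds the RNG.
anneal_logic <- function(X, y, max_leaves, iters = 10000L) {
  p <- ncol(X)
  cur_tree <- bare_leaf(p)
  cur_leaves <- 1L
  cur <- logic_objective(y, eval_btree(cur_tree, X))
  best_tree <- cur_tree
  best <- cur
  # pilot: typical uphill RSS jump -> T0 with ~50% uphill acceptance
  uphill <- numeric(0)
  pilot_tree <- cur_tree
  pilot_leaves <- 1L
  pilot_obj <- cur
  for (i in seq_len(100L)) {
    cand <- propose_btree_move(pilot_tree, pilot_leaves, p, max_leaves)
    obj <- logic_objective(y, eval_btree(cand$tree, X))
    d <- obj$rss - pilot_obj$rss
    if (d > 0) uphill <- c(uphill, d)
    pilot_tree <- cand$tree
    pilot_leaves <- cand$n_leaves
    pilot_obj <- obj
    if (obj$rss < best$rss) {
      best_tree <- cand$tree
      best <- obj
    }
  }
  t0 <- if (length(uphill)) stats::median(uphill) / log(2) else stats::var(y)
  t0 <- max(t0, .Machine$double.eps)
  cool <- (1e-6)^(1 / iters)   # T_final = 1e-6 * T0
  temp <- t0
  for (i in seq_len(iters)) {
    cand <- propose_btree_move(cur_tree, cur_leaves, p, max_leaves)
    obj <- logic_objective(y, eval_btree(cand$tree, X))
    d <- obj$rss - cur$rss
    if (d <= 0 || stats::runif(1) < exp(-d / temp)) {
      cur_tree <- cand$tree
      cur_leaves <- cand$n_leaves
      cur <- obj
      if (cur$rss < best$rss - 1e-12) {
        best_tree <- cur_tree
        best <- cur
      }
    }
    temp <- temp * cool
  }
  list(tree = best_tree, rss = best$rss, b0 = best$b0, b1 = best$b1,
       degenerate = best$degenerate)
}

#' Logic regression by simulated annealing
#'
#' Fits `y ~ b0 + b1 * L(X)` where `L` is a Boolean AND/OR tree over
#' the mutation indicators (leaves possibly negated). The tree is found
#' by simulated annealing; the leaf budget is selected by internal
#' cross-validation over 0..`max_leaves` with the 1-SE parsimony rule
#' (budget 0 = intercept only, covering pure-noise outcomes).
#'
#' @inheritParams fit_lm_main
#' @param max_leaves largest leaf budget considered (default 8)
#' @param anneal_iter annealing iterations for the final full-data
#'   search
#' @param inner_iter annealing iterations inside the internal CV
#'   (shorter: the per-budget searches are small, and the full-data
#'   search is rerun at the chosen budget with `anneal_iter`)
#' @param inner_folds internal CV folds
#' @param seed integer seed or NULL
#' @return a `fitted_learner`
#' @export
fit_logicreg <- function(dataset, max_leaves = 8L, anneal_iter = 10000L,
                         inner_iter = 1000L, inner_folds = 5L, seed = NULL) {
  stopifnot(inherits(dataset, "geno_dataset"), max_leaves >= 1)
  G <- dataset$genotype
  y <- dataset$outcome
  n <- nrow(G)
  with_seed(seed %||% stable_hash("logicreg_default"), {
    folds <- make_folds(n, min(inner_folds, n), sample.int(2^28, 1L))
    sizes <- 0:max_leaves
    fold_mse <- matrix(NA_real_, folds$k, length(sizes))
    for (f in seq_len(folds$k)) {
      tr <- folds$fold_index != f
      ytr <- y[tr]
      for (si in seq_along(sizes)) {
        s <- sizes[si]
        if (s == 0L) {
          pred <- rep(mean(ytr), sum(!tr))
        } else {
          fit <- anneal_logic(G[tr, , drop = FALSE], ytr, s, inner_iter)
          pred <- fit$b0 + fit$b1 * eval_btree(fit$tree, G[!tr, , drop = FALSE])
        }
        fold_mse[f, si] <- mean((y[!tr] - pred)^2)
      }
    }
    cv_mean <- colMeans(fold_mse)
    cv_se <- apply(fold_mse, 2, stats::sd) / sqrt(folds$k)
    size_star <- sizes[select_size_1se(cv_mean, cv_se) + 1L]

    if (size_star == 0L) {
      model <- list(tree = NULL, b0 = mean(y), b1 = 0, size = 0L)
      sel <- character(0)
    } else {
      fit <- anneal_logic(G, y, size_star, anneal_iter)
      if (fit$degenerate || abs(fit$b1) < 1e-12) {
        model <- list(tree = NULL, b0 = mean(y), b1 = 0, size = 0L)
        sel <- character(0)
      } else {
        tree <- classify_btree(fit$tree)
        model <- list(tree = tree, b0 = fit$b0, b1 = fit$b1,
                      size = btree_n_leaves(tree))
        sel <- colnames(G)[btree_vars(tree)]
      }
    }
    new_fitted_learner("logicreg", model, colnames(G), sel)
  })
}
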