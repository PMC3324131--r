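# The six candidate learners behind one fit / predict /
# selected-features contract. Roster order is also the tie-break order
# for the discrete Super Learner.

LEARNER_ORDER <- c("lm1", "lm2", "rf", "dsa", "cart", "logicreg")

LEARNER_DISPLAY <- c(lm1 = "LM(1)", lm2 = "LM(2)", rf = "Random Forest",
                     dsa = "D/S/A", cart = "CART", logicreg = "LogicReg")

#' Candidate learner specification
#'
#' @param name one of `"lm1"`, `"lm2"`, `"cart"`, `"rf"`, `"dsa"`,
#'   `"logicreg"`
#' @param hyper named list of hyperparameters passed to the learner's
#'   fit function (defaults are the published tuning: `cp = 0.01`,
#'   `n_trees = 1000`, `m_try = p/3`, `maxsize = 2p`, `maxorderint = 2`,
#'   `maxsumofpow = 2`)
#' @param seed integer seed for the stochastic learners, or NULL
#' @return object of class `learner_spec`
#' @export
learner_spec <- function(name, hyper = list(), seed = NULL) {
  name <- match.arg(tolower(name), LEARNER_ORDER)
  allowed <- switch(name,
    lm1 = character(0),
    lm2 = character(0),
    cart = c("cp", "min_split", "min_bucket"),
    rf = c("n_trees", "m_try", "bootstrap", "min_split", "min_bucket"),
    dsa = c("maxsize", "maxorderint", "maxsumofpow", "inner_folds"),
    logicreg = c("max_leaves", "anneal_iter", "inner_iter", "inner_folds"))
  bad <- setdiff(names(hyper), allowed)
  if (length(bad)) {
    stop_slgeno(sprintf("unknown hyperparameter(s) for %s: %s", name,
                        paste(bad, collapse = ", ")),
                "slgeno_parameter_error")
  }
  structure(list(name = name, hyper = hyper,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "learner_spec")
}

#' Fit a learner from its specification
#' @param spec a [learner_spec()]
#' @param dataset a [geno_dataset()]
#' @return a `fitted_learner`
#' @export
fit_learner <- function(spec, dataset) {
  stopifnot(inherits(spec, "learner_spec"))
  args <- c(list(dataset), spec$hyper)
  if (spec$name %in% c("rf", "dsa", "logicreg")) args$seed <- spec$seed
  do.call(switch(spec$name,
                 lm1 = fit_lm_main, lm2 = fit_lm_interact,
                 cart = fit_cart, rf = fit_random_forest,
                 dsa = fit_dsa, logicreg = fit_logicreg),
          args)
}

new_fitted_learner <- function(name, model, labels, selected) {
  structure(list(name = name, model = model, labels = labels,
                 selected_features = selected),
            class = "fitted_learner")
}

#' @export
print.fitted_learner <- function(x, ...) {
  cat(sprintf("<fitted_learner> %s; %d training mutation(s); selected: %s\n",
              LEARNER_DISPLAY[[x$name]], length(x$labels),
              if (length(x$selected_features))
                paste(x$selected_features, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Mutations actually used by a fitted model
#' @param object a `fitted_learner` or `super_learner`
#' @return character vector of canonical mutation labels
#' @export
selected_features <- function(object) UseMethod("selected_features")

#' @export
selected_features.fitted_learner <- function(object) object$selected_features

as_genotype <- function(newdata, labels) {
  G <- if (inherits(newdata, "geno_dataset")) newdata$genotype else newdata
  if (!all(labels %in% colnames(G))) {
    stop_slgeno("newdata is missing training mutation columns",
                "slgeno_format_error")
  }
  G[, labels, drop = FALSE]
}

#' Predict from a fitted learner
#' @param object a `fitted_learner`
#' @param newdata a `geno_dataset` or genotype matrix carrying the
#'   training mutation columns
#' @param ... unused
#' @return numeric predictions, one per row
#' @export
predict.fitted_learner <- function(object, newdata, ...) {
  G <- as_genotype(newdata, object$labels)
  m <- object$model
  unname(switch(object$name,
    lm1 = drop(cbind(1, G) %*% m$beta),
    lm2 = drop(cbind(1, G, interaction_columns(G)) %*% m$beta),
    cart = predict_tree(m$tree, G),
    rf = {
      preds <- vapply(m$trees, function(tr) predict_tree(tr, G),
                      numeric(nrow(G)))
      if (nrow(G) == 1L) mean(preds) else rowMeans(preds)
    },
    dsa = predict_dsa_model(m, G),
    logicreg = {
      if (is.null(m$tree)) rep(m$b0, nrow(G))
      else m$b0 + m$b1 * eval_btree(m$tree, G)
    }))
}

# Minimum-norm least squares via SVD (deterministic for rank-deficient
# designs such as the two-way-interaction model at n < p).
min_norm_ls <- function(X, y) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  rank <- sum(sv$d > tol)
  beta <- drop(sv$v %*% (dinv * crossprod(sv$u, y)))
  list(beta = beta, rank = rank, rank_deficient = rank < ncol(X))
}

#' Least squares on all main terms — LM(1)
#'
#' Ordinary least squares of the outcome on an intercept plus every
#' mutation indicator, with no variable selection. Rank-deficient
#' designs get the minimum-norm solution.
#'
#' @param dataset a [geno_dataset()]
#' @return a `fitted_learner`
#' @export
fit_lm_main <- function(dataset) {
  stopifnot(inherits(dataset, "geno_dataset"), nrow(dataset$genotype) >= 2)
  G <- dataset$genotype
  fit <- min_norm_ls(cbind(1, G), dataset$outcome)
  if (all(apply(G, 2, function(col) length(unique(col)) == 1L))) {
    warning("all-constant design: LM(1) reduces to an intercept-only fit",
            call. = FALSE)
  }
  sel <- colnames(G)[abs(fit$beta[-1]) > 1e-10]
  new_fitted_learner("lm1", list(beta = fit$beta), colnames(G), sel)
}

interaction_columns <- function(G) {
  p <- ncol(G)
  if (p < 2L) {
    return(matrix(numeric(0), nrow(G), 0))
  }
  pairs <- utils::combn(p, 2)
  out <- G[, pairs[1, ], drop = FALSE] * G[, pairs[2, ], drop = FALSE]
  colnames(out) <- paste(colnames(G)[pairs[1, ]], colnames(G)[pairs[2, ]],
                         sep = ":")
  out
}

#' Least squares with all two-way interactions — LM(2)
#'
#' Intercept + p main terms + p(p-1)/2 pairwise products. With ten
#' mutations that is 56 parameters, more than a hundred-patient trial
#' can identify; the minimum-norm solution keeps the fit deterministic
#' and reproduces the characteristic in-sample overfit.
#'
#' @inheritParams fit_lm_main
#' @return a `fitted_learner`
#' @export
fit_lm_interact <- function(dataset) {
  stopifnot(inherits(dataset, "geno_dataset"), nrow(dataset$genotype) >= 2)
  G <- dataset$genotype
  X <- cbind(1, G, interaction_columns(G))
  fit <- min_norm_ls(X, dataset$outcome)
  if (fit$rank_deficient) {
    sl_log("info", sprintf(
      "LM(2) design rank %d < %d parameters; minimum-norm solution used",
      fit$rank, ncol(X)))
  }
  main <- abs(fit$beta[1 + seq_len(ncol(G))]) > 1e-10
  inter <- abs(fit$beta[-seq_len(1 + ncol(G))]) > 1e-10
  inter_vars <- unique(unlist(strsplit(
    colnames(X)[-seq_len(1 + ncol(G))][inter], ":", fixed = TRUE)))
  sel <- colnames(G)[main | colnames(G) %in% inter_vars]
  new_fitted_learner("lm2", list(beta = fit$beta), colnames(G), sel)
}

#' Regression tree — CART
#'
#' Binary recursive partitioning with leaf-mean predictions. A split is
#' retained only when it reduces the training error by at least
#' `cp` times the root RSS (the cost-complexity rule); `min_bucket`
#' keeps leaves from degenerating at trial scale.
#'
#' @inheritParams fit_lm_main
#' @param cp complexity parameter (default 0.01, the published tuning)
#' @param min_split minimum node size to attempt a split
#' @param min_bucket minimum observations per leaf
#' @return a `fitted_learner`
#' @export
fit_cart <- function(dataset, cp = 0.01, min_split = 10L, min_bucket = 5L) {
  stopifnot(inherits(dataset, "geno_dataset"), nrow(dataset$genotype) >= 2,
            cp >= 0)
  G <- dataset$genotype
  tree <- grow_tree(G, dataset$outcome, mtry = ncol(G),
                    min_split = min_split, min_bucket = min_bucket, cp = cp)
  new_fitted_learner("cart", list(tree = tree, cp = cp), colnames(G),
                     colnames(G)[tree_vars(tree)])
}

#' Bagged regression forest — Random Forest
#'
#' Bootstrap-aggregated unpruned regression trees with `m_try`
#' covariates sampled at each node; predictions average over trees.
#' Defaults are the published tuning: 1,000 trees and
#' `m_try = floor(p / 3)` (3 for the ten-mutation panel).
#'
#' @inheritParams fit_lm_main
#' @param n_trees number of trees
#' @param m_try covariates sampled per node; default `floor(p / 3)`,
#'   at least 1
#' @param seed integer seed or NULL
#' @param bootstrap draw bootstrap resamples (disable only for the
#'   single-tree sanity bridge to CART)
#' @param min_split,min_bucket node-size controls for the unpruned trees
#' @return a `fitted_learner`
#' @export
fit_random_forest <- function(dataset, n_trees = 1000L, m_try = NULL,
                              seed = NULL, bootstrap = TRUE,
                              min_split = 5L, min_bucket = 1L) {
  stopifnot(inherits(dataset, "geno_dataset"), n_trees >= 1)
  G <- dataset$genotype
  y <- dataset$outcome
  p <- ncol(G)
  m_try <- m_try %||% max(1L, floor(p / 3))
  if (m_try < 1 || m_try > p) {
    stop_slgeno(sprintf("m_try = %d outside 1..%d", m_try, p),
                "slgeno_parameter_error")
  }
  n <- nrow(G)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    grow_tree(G, y, mtry = m_try, min_split = min_split,
              min_bucket = min_bucket, cp = 0,
              idx = idx, root_rss = sum((y[idx] - mean(y[idx]))^2))
  }))
  used <- sort(unique(unlist(lapply(trees, tree_vars))))
  new_fitted_learner("rf",
                     list(trees = trees, m_try = m_try, n_trees = n_trees),
                     colnames(G), colnames(G)[used])
}
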