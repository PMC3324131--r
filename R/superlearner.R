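# Discrete and weighted Super Learner on the level-one matrix. Weights
# live on the probability simplex {w >= 0, sum w = 1}: under squared
# error the fit is a non-negativity-constrained quadratic program; under
# 1-R the correlation objective is scale-invariant and non-convex on
# the simplex, so a multi-start projected-gradient ascent is used.

SL_ROSTERS <- list(SL5 = c("lm1", "lm2", "rf", "dsa", "cart"),
                   SL6 = c("lm1", "lm2", "rf", "dsa", "cart", "logicreg"))

#' Candidate roster of a Super Learner
#' @param roster `"SL5"` (LM(1), LM(2), Random Forest, D/S/A, CART) or
#'   `"SL6"` (SL5 plus Logic Regression)
#' @return character vector of learner names in roster (tie-break) order
#' @export
sl_roster <- function(roster = c("SL5", "SL6")) {
  SL_ROSTERS[[match.arg(roster)]]
}

#' Discrete Super Learner selection
#'
#' Returns the learner with the smallest mean cross-validated risk; on
#' exact ties, the one earliest in the fixed roster order (LM(1),
#' LM(2), Random Forest, D/S/A, CART, Logic Regression).
#'
#' @param table a [cv_risk_table()], or a named numeric vector of mean
#'   risks
#' @return learner name
#' @export
discrete_super_learner <- function(table) {
  risks <- if (inherits(table, "cv_risk_table")) {
    stats::setNames(table$mean_risk, table$learner)
  } else {
    table
  }
  stopifnot(length(risks) >= 1)
  ord <- order(match(names(risks), LEARNER_ORDER))
  risks <- risks[ord]
  names(risks)[which.min(round(risks, 10))]
}

project_simplex <- function(v) {
  # Euclidean projection onto {w >= 0, sum w = 1} (sort-based)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  w <- pmax(v + (1 - css[rho]) / rho, 0)
  w / sum(w)
}

fit_weights_sqe <- function(Z, y) {
  L <- ncol(Z)
  D <- crossprod(Z)
  D <- D + diag(1e-8 * max(diag(D)), L)  # ridge for duplicate columns
  A <- cbind(rep(1, L), diag(L))
  sol <- quadprog::solve.QP(D, crossprod(Z, y), A, c(1, rep(0, L)), meq = 1)
  w <- sol$solution
  w[w < 1e-8] <- 0           # sparse report, then renormalize
  w / sum(w)
}

fit_weights_one_minus_r <- function(Z, y, n_starts = 20L, seed = NULL) {
  L <- ncol(Z)
  a <- drop(stats::cov(Z, y))
  B <- stats::cov(Z)
  gfun <- function(w) {
    s2 <- drop(t(w) %*% B %*% w)
    if (s2 <= 0) return(list(val = -Inf, grad = rep(0, L)))
    s <- sqrt(s2)
    list(val = sum(a * w) / s,
         grad = a / s - sum(a * w) * drop(B %*% w) / s^3)
  }
  starts <- c(lapply(seq_len(L), function(j) {
    w <- rep(0, L); w[j] <- 1; w
  }), list(rep(1 / L, L)))
  extra <- n_starts - length(starts)
  if (extra > 0) {
    rand <- with_seed(seed %||% stable_hash("sl_weights"), {
      lapply(seq_len(extra), function(i) {
        e <- stats::rexp(L)
        e / sum(e)
      })
    })
    starts <- c(starts, rand)
  }
  best_w <- NULL
  best_val <- -Inf
  for (w in starts) {
    g <- gfun(w)
    if (!is.finite(g$val)) next
    step <- 1
    for (it in seq_len(500L)) {
      improved <- FALSE
      while (step > 1e-12) {
        cand <- project_simplex(w + step * g$grad)
        gc_ <- gfun(cand)
        if (gc_$val > g$val + 1e-10) {
          w <- cand
          g <- gc_
          improved <- TRUE
          step <- min(step * 2, 1e3)
          break
        }
        step <- step / 2
      }
      if (!improved) break
    }
    # best-so-far across starts never worsens
    if (g$val > best_val) {
      best_val <- g$val
      best_w <- w
    }
  }
  if (is.null(best_w)) {
    warning("all candidate combinations are constant: uniform weights",
            call. = FALSE)
    best_w <- rep(1 / L, L)
  }
  best_w
}

#' Fit Super Learner weights on the level-one matrix
#'
#' Minimizes `risk(loss, y, Z w)` over the simplex. Squared error is
#' solved exactly as a quadratic program; the 1-R objective is
#' maximized by projected-gradient ascent from 20 starts (the simplex
#' vertices, the barycenter, and seeded random points).
#'
#' @param Z n x L [level_one_matrix()] (or any prediction matrix)
#' @param y observed outcomes
#' @param loss `"sqe"` or `"one_minus_r"`
#' @param seed seed for the random multi-starts (1-R only)
#' @return object of class `sl_weights`: list with `weights` (named,
#'   non-negative, summing to 1), `loss`, `risk` (achieved pooled
#'   level-one risk)
#' @export
fit_sl_weights <- function(Z, y, loss = "sqe", seed = NULL) {
  loss <- normalize_loss(loss)
  stopifnot(is.matrix(Z), ncol(Z) >= 1, nrow(Z) == length(y))
  if (all(apply(Z, 2, stats::sd) == 0)) {
    warning("all level-one columns constant: uniform weights", call. = FALSE)
    w <- rep(1 / ncol(Z), ncol(Z))
  } else {
    w <- if (loss == "sqe") {
      fit_weights_sqe(Z, y)
    } else {
      fit_weights_one_minus_r(Z, y, seed = seed)
    }
    # polish: a simplex vertex (single learner) is always feasible, so
    # the returned combination is never worse than the best single column
    cand <- c(list(w), lapply(seq_len(ncol(Z)), function(j) {
      v <- rep(0, ncol(Z))
      v[j] <- 1
      v
    }))
    cand_risk <- vapply(cand, function(wi) {
      suppressWarnings(risk(loss, y, drop(Z %*% wi)))
    }, 0)
    w <- cand[[which.min(cand_risk)]]
  }
  names(w) <- colnames(Z)
  achieved <- suppressWarnings(risk(loss, y, drop(Z %*% w)))
  structure(list(weights = w, loss = loss, risk = achieved),
            class = "sl_weights")
}

#' @export
print.sl_weights <- function(x, ...) {
  cat(sprintf("<sl_weights> loss %s, level-one risk %.4f\n", x$loss, x$risk))
  print(round(x$weights, 4))
  invisible(x)
}

#' Serialize Super Learner weights to JSON
#' @param weights an `sl_weights`
#' @param path output path
#' @param roster,seed optional metadata recorded alongside
#' @export
write_sl_weights <- function(weights, path, roster = NULL, seed = NULL) {
  jsonlite::write_json(
    list(weights = as.list(weights$weights), loss = weights$loss,
         risk = weights$risk, roster = roster, seed = seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Build a weighted Super Learner
#'
#' Computes the level-one matrix for the roster's candidates by k-fold
#' cross-validation, fits simplex weights under the loss, and refits
#' every candidate on the full dataset. Predictions are `Z_new w` where
#' `Z_new` stacks the candidates' full-data predictions.
#'
#' @param dataset a [geno_dataset()]
#' @param roster `"SL5"` or `"SL6"`
#' @param k number of folds
#' @param loss `"sqe"` or `"one_minus_r"`
#' @param seed master seed (fans out to folds, stochastic learners and
#'   the weight multi-starts)
#' @param learner_args named list of hyperparameter overrides per
#'   learner name (e.g. `list(rf = list(n_trees = 100))`)
#' @param specs optional full override of the candidate
#'   [learner_spec()] list
#' @param Z optional precomputed level-one matrix for the roster (must
#'   carry its `"folds"` attribute)
#' @return object of class `super_learner`
#' @export
build_super_learner <- function(dataset, roster = "SL5", k = 10L,
                                loss = "sqe", seed = 1L,
                                learner_args = list(), specs = NULL,
                                Z = NULL) {
  roster <- match.arg(roster, names(SL_ROSTERS))
  loss <- normalize_loss(loss)
  names_ <- sl_roster(roster)
  if (is.null(specs)) {
    specs <- lapply(names_, function(nm) {
      learner_spec(nm, hyper = learner_args[[nm]] %||% list(),
                   seed = derive_seed(seed, nm))
    })
  }
  if (is.null(Z)) {
    folds <- make_folds(nrow(dataset$genotype), k, derive_seed(seed, "folds", k))
    Z <- level_one_matrix(specs, dataset, folds)
  } else {
    folds <- attr(Z, "folds")
    stopifnot(!is.null(folds))
  }
  weights <- fit_sl_weights(Z, dataset$outcome, loss,
                            seed = derive_seed(seed, "weights"))
  full_fits <- lapply(specs, fit_learner, dataset = dataset)
  names(full_fits) <- vapply(specs, `[[`, "", "name")
  structure(list(roster = roster, weights = weights, full_fits = full_fits,
                 level_one = Z, folds = folds, loss = loss, seed = seed),
            class = "super_learner")
}

#' @export
predict.super_learner <- function(object, newdata, ...) {
  Z_new <- vapply(object$full_fits, predict,
                  numeric(if (inherits(newdata, "geno_dataset"))
                    nrow(newdata$genotype) else nrow(newdata)),
                  newdata = newdata)
  if (is.null(dim(Z_new))) Z_new <- matrix(Z_new, nrow = 1)
  unname(drop(Z_new %*% object$weights$weights))
}

#' @export
selected_features.super_learner <- function(object) {
  active <- names(object$weights$weights)[object$weights$weights > 0]
  sort(unique(unlist(lapply(object$full_fits[active], selected_features))))
}

#' @export
print.super_learner <- function(x, ...) {
  cat(sprintf("<super_learner> %s, loss %s, k = %d\n",
              x$roster, x$loss, x$folds$k))
  print(round(x$weights$weights, 4))
  invisible(x)
}

#' Level-one risk of a weighted combination
#'
#' The risk of `Z w` against the observed outcomes: pooled by default
#' (the functional the weights minimize), or per-fold-averaged when a
#' fold assignment is supplied (the convention of the learner rows in
#' the CV risk tables). An honest variant that cross-validates the
#' whole Super Learner is [honest_sl_risk()].
#'
#' @param model a `super_learner` or `sl_weights`
#' @param Z level-one matrix the weights were fitted on (defaults to
#'   the model's own)
#' @param y observed outcomes
#' @param loss `"sqe"` or `"one_minus_r"`
#' @param folds optional [make_folds()] assignment for per-fold
#'   averaging
#' @return risk value
#' @export
sl_level_one_risk <- function(model, Z = NULL, y = NULL, loss = NULL,
                              folds = NULL) {
  w <- if (inherits(model, "super_learner")) model$weights else model
  stopifnot(inherits(w, "sl_weights"))
  if (inherits(model, "super_learner")) {
    Z <- Z %||% model$level_one
  }
  loss <- normalize_loss(loss %||% w$loss)
  pred <- drop(Z %*% w$weights)
  if (is.null(folds)) {
    risk(loss, y, pred)
  } else {
    risk_by_fold(loss, y, pred, folds)$mean_risk
  }
}

#' Honest cross-validated risk of the whole Super Learner
#'
#' Wraps an outer cross-validation around the entire Super Learner
#' (inner level-one construction, weight fitting and candidate refits
#' happen inside each outer training set), so the reported risk is not
#' optimistic about the weight fitting.
#'
#' @inheritParams build_super_learner
#' @param outer_k outer fold count
#' @return list with `fold_risks`, `mean_risk`
#' @export
honest_sl_risk <- function(dataset, roster = "SL5", k = 10L, loss = "sqe",
                           seed = 1L, outer_k = 10L, learner_args = list()) {
  n <- nrow(dataset$genotype)
  outer <- make_folds(n, outer_k, derive_seed(seed, "outer_folds"))
  pred <- numeric(n)
  for (f in seq_len(outer$k)) {
    v <- outer$fold_index == f
    train <- geno_dataset(dataset$genotype[!v, , drop = FALSE],
                          dataset$outcome[!v])
    sl <- build_super_learner(train, roster, min(k, sum(!v)), loss,
                              seed = derive_seed(seed, "honest", f),
                              learner_args = learner_args)
    pred[v] <- predict(sl, dataset$genotype[v, , drop = FALSE])
  }
  r <- risk_by_fold(loss, dataset$outcome, pred, outer)
  list(fold_risks = r$fold_risks, mean_risk = r$mean_risk)
}
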