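# Deletion / Substitution / Addition search over linear models whose
# terms are products of binary covariates. On a 0/1 design x^2 = x, so
# powers are canonicalized to 1 and maxsumofpow effectively bounds the
# interaction order together with maxorderint. The best model of every
# size 0..maxsize is recorded; the final size comes from internal
# cross-validation (1-SE parsimony rule).

# Candidate term universe: all products of 1..maxorder distinct
# covariates. Returns list(vars = list of index vectors, labels).
dsa_term_universe <- function(p, maxorderint, maxsumofpow, labels) {
  maxorder <- min(maxorderint, maxsumofpow, p)
  vars <- list()
  for (ord in seq_len(maxorder)) {
    cmb <- utils::combn(p, ord)
    vars <- c(vars, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  list(vars = vars,
       labels = vapply(vars, function(v) paste(labels[v], collapse = ":"),
                       character(1)))
}

dsa_term_matrix <- function(G, term_vars) {
  out <- matrix(1, nrow(G), length(term_vars))
  for (j in seq_along(term_vars)) {
    for (v in term_vars[[j]]) out[, j] <- out[, j] * G[, v]
  }
  out
}

# Fast RSS of y on intercept + a term subset, via precomputed Gram
# pieces with a tiny ridge for numerical definiteness.
make_rss_fun <- function(TC, y) {
  A <- crossprod(cbind(1, TC))
  b <- crossprod(cbind(1, TC), y)
  yy <- sum(y^2)
  ridge <- 1e-10 * max(diag(A))
  function(S) {
    # S: indices into TC; intercept always included (Gram index 1)
    i <- c(1L, S + 1L)
    Ai <- A[i, i, drop = FALSE]
    diag(Ai) <- diag(Ai) + ridge
    R <- chol(Ai)
    z <- backsolve(R, backsolve(R, b[i], transpose = TRUE))
    list(rss = max(yy - sum(b[i] * z), 0), coef = z)
  }
}

# One D/S/A search. Returns best (lowest-RSS) model of size at most s
# for every s in 0..maxsize: list of list(rss, terms).
dsa_search <- function(TC, y, maxsize, tol = 1e-9, max_moves = 1000L) {
  n_terms <- ncol(TC)
  rss_fun <- make_rss_fun(TC, y)
  null_rss <- sum((y - mean(y))^2)
  best <- vector("list", maxsize + 1L)
  best[[1]] <- list(rss = null_rss, terms = integer(0))
  record <- function(S, rss) {
    s <- length(S)
    if (s <= maxsize && (is.null(best[[s + 1]]) || rss < best[[s + 1]]$rss)) {
      best[[s + 1]] <<- list(rss = rss, terms = sort(S))
    }
  }
  S <- integer(0)
  cur_rss <- null_rss
  moves <- 0L
  while (moves < max_moves) {
    moves <- moves + 1L
    s <- length(S)
    # Deletion: accept if it beats the best smaller model
    if (s >= 1L) {
      del_rss <- vapply(seq_len(s), function(i) rss_fun(S[-i])$rss, 0)
      i <- which.min(del_rss)
      if (del_rss[i] < best[[s]]$rss - tol) {
        S <- S[-i]
        cur_rss <- del_rss[i]
        record(S, cur_rss)
        next
      }
    }
    # Substitution: accept if it beats the best same-size model
    if (s >= 1L && s < n_terms) {
      repl <- setdiff(seq_len(n_terms), S)
      sub_best <- NULL
      for (i in seq_len(s)) {
        for (cnd in repl) {
          Snew <- S
          Snew[i] <- cnd
          r <- rss_fun(Snew)$rss
          if (is.null(sub_best) || r < sub_best$rss) {
            sub_best <- list(rss = r, terms = Snew)
          }
        }
      }
      if (!is.null(sub_best) && sub_best$rss < best[[s + 1]]$rss - tol) {
        S <- sub_best$terms
        cur_rss <- sub_best$rss
        record(S, cur_rss)
        next
      }
    }
    # Addition
    if (s < maxsize && s < n_terms) {
      add <- setdiff(seq_len(n_terms), S)
      add_rss <- vapply(add, function(cnd) rss_fun(c(S, cnd))$rss, 0)
      i <- which.min(add_rss)
      S <- c(S, add[i])
      cur_rss <- add_rss[i]
      record(S, cur_rss)
      next
    }
    break
  }
  # best model "of size s" = best with at most s terms, so the RSS path
  # is non-increasing in s by construction
  for (s in seq_len(maxsize)) {
    if (is.null(best[[s + 1]]) || best[[s + 1]]$rss > best[[s]]$rss) {
      best[[s + 1]] <- best[[s]]
    }
  }
  best
}

# 1-SE parsimony rule: smallest size whose CV risk is within one
# standard error of the minimizer's.
select_size_1se <- function(cv_mean, cv_se) {
  smin <- which.min(cv_mean)
  cutoff <- cv_mean[smin] + cv_se[smin]
  which(cv_mean <= cutoff + 1e-12)[1] - 1L
}

#' Deletion/Substitution/Addition polynomial search — D/S/A
#'
#' Best-subset-style search over linear models whose terms are products
#' of binary mutation indicators: single-term deletions, substitutions
#' and additions are proposed from the current term set, the best model
#' of every size 0..`maxsize` is recorded, and the final size is chosen
#' by internal cross-validation (smallest size within one standard
#' error of the CV-risk minimizer). Defaults follow the published
#' tuning: `maxsize = 2p`, `maxorderint = 2`, `maxsumofpow = 2`, all
#' three move types allowed.
#'
#' @inheritParams fit_lm_main
#' @param maxsize maximum number of terms (default twice the number of
#'   mutations)
#' @param maxorderint maximum distinct covariates per term
#' @param maxsumofpow maximum total power per term; on binary
#'   covariates powers are canonicalized to 1, so this caps the
#'   interaction order together with `maxorderint`
#' @param inner_folds internal CV folds for size selection
#' @param seed integer seed for the internal CV split
#' @return a `fitted_learner`
#' @export
fit_dsa <- function(dataset, maxsize = NULL, maxorderint = 2L,
                    maxsumofpow = 2L, inner_folds = 5L, seed = NULL) {
  stopifnot(inherits(dataset, "geno_dataset"))
  G <- dataset$genotype
  y <- dataset$outcome
  p <- ncol(G)
  n <- nrow(G)
  maxsize <- if (is.null(maxsize)) 2L * p else as.integer(maxsize)
  if (maxsize < 0) {
    stop_slgeno("maxsize must be >= 0", "slgeno_parameter_error")
  }
  if (maxsumofpow > maxorderint) {
    sl_log("debug",
           "binary covariates: powers canonicalized to 1, maxsumofpow caps interaction order")
  }
  uni <- dsa_term_universe(p, maxorderint, maxsumofpow, colnames(G))
  TC <- dsa_term_matrix(G, uni$vars)
  maxsize <- min(maxsize, length(uni$vars))

  size_star <- 0L
  if (maxsize > 0L) {
    folds <- make_folds(n, min(inner_folds, n),
                        derive_seed(seed %||% stable_hash("dsa_default"),
                                    "dsa_cv"))
    fold_mse <- matrix(NA_real_, folds$k, maxsize + 1L)
    for (f in seq_len(folds$k)) {
      tr <- folds$fold_index != f
      rss_tr <- make_rss_fun(TC[tr, , drop = FALSE], y[tr])
      best_tr <- dsa_search(TC[tr, , drop = FALSE], y[tr], maxsize)
      for (s in 0:maxsize) {
        S <- best_tr[[s + 1]]$terms
        cf <- rss_tr(S)$coef
        pred <- drop(cbind(1, TC[!tr, S, drop = FALSE]) %*% cf)
        fold_mse[f, s + 1] <- mean((y[!tr] - pred)^2)
      }
    }
    cv_mean <- colMeans(fold_mse)
    cv_se <- apply(fold_mse, 2, stats::sd) / sqrt(folds$k)
    size_star <- select_size_1se(cv_mean, cv_se)
  }

  best <- dsa_search(TC, y, maxsize)
  S <- best[[size_star + 1]]$terms
  fit <- min_norm_ls(cbind(1, TC[, S, drop = FALSE]), y)
  model <- list(term_vars = uni$vars[S], term_labels = uni$labels[S],
                beta = fit$beta, size = length(S), maxsize = maxsize,
                maxorderint = maxorderint, maxsumofpow = maxsumofpow)
  sel_idx <- sort(unique(unlist(uni$vars[S])))
  new_fitted_learner("dsa", model, colnames(G), colnames(G)[sel_idx])
}

predict_dsa_model <- function(model, G) {
  TC <- dsa_term_matrix(G, model$term_vars)
  drop(cbind(1, TC) %*% model$beta)
}
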