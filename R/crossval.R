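#' k-fold assignment
#'
#' Partitions `n` patients into `k` mutually exclusive, exhaustive folds
#' of as nearly equal size as possible, uniformly at random given the
#' seed (unstratified).
#'
#' @param n patient count
#' @param k fold count, `2 <= k <= n`
#' @param seed integer seed (mandatory, for reproducibility)
#' @return object of class `fold_assignment`: list with `k`,
#'   `fold_index` (per-patient fold in 1..k), `seed`
#' @export
make_folds <- function(n, k, seed) {
  if (k < 2 || k > n) {
    stop_slgeno(sprintf("fold count k = %d outside 2..n = %d", k, n),
                "slgeno_parameter_error")
  }
  stopifnot(!is.null(seed))
  fold_index <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  structure(list(k = as.integer(k), fold_index = fold_index,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

LOSS_NAMES <- c("sqe", "one_minus_r")

normalize_loss <- function(loss) {
  loss <- tolower(as.character(loss))
  loss <- c(sqe = "sqe", one_minus_r = "one_minus_r")[[match.arg(loss, LOSS_NAMES)]]
  loss
}

#' Loss-based risk of predictions
#'
#' `"sqe"` is the mean squared difference between observed and
#' predicted outcome (unbounded below by 0); `"one_minus_r"` is one
#' minus the Pearson correlation between them, bounded in \[0, 2\]. A
#' constant observation or prediction vector has no defined
#' correlation: by convention R = 0, risk 1, with a warning.
#'
#' @param loss `"sqe"` or `"one_minus_r"`
#' @param y observed outcomes
#' @param pred predictions, same length
#' @return non-negative risk
#' @export
risk <- function(loss, y, pred) {
  loss <- normalize_loss(loss)
  stopifnot(length(y) == length(pred), length(y) >= 1,
            all(is.finite(y)), all(is.finite(pred)))
  if (loss == "sqe") {
    return(mean((y - pred)^2))
  }
  if (length(y) < 2) {
    stop_slgeno("one_minus_r needs at least 2 observations",
                "slgeno_parameter_error")
  }
  if (stats::sd(y) == 0 || stats::sd(pred) == 0) {
    warning("constant observations or predictions: R taken as 0, risk 1",
            call. = FALSE)
    return(1)
  }
  1 - stats::cor(y, pred)
}

# Risk of a level-one column given the fold assignment: per-fold risks
# averaged (the default, mirroring "the k risks over the k validation
# sets are averaged"), or pooled over all patients when pooled = TRUE.
risk_by_fold <- function(loss, y, pred, folds, pooled = FALSE) {
  if (pooled) {
    r <- risk(loss, y, pred)
    return(list(fold_risks = r, mean_risk = r))
  }
  fr <- vapply(seq_len(folds$k), function(f) {
    v <- folds$fold_index == f
    risk(loss, y[v], pred[v])
  }, 0)
  list(fold_risks = fr, mean_risk = mean(fr))
}

#' Cross-validated risk of one learner
#'
#' For each fold the learner is fitted on the complement and predicts
#' the fold; fold risks are averaged into the cross-validated risk, and
#' the out-of-fold predictions are assembled into the learner's
#' level-one column.
#'
#' @param spec a [learner_spec()]
#' @param dataset a [geno_dataset()]
#' @param folds a [make_folds()] assignment over the dataset
#' @param loss `"sqe"` or `"one_minus_r"`
#' @param pooled compute one pooled risk over all out-of-fold
#'   predictions instead of averaging per-fold risks (sensitivity
#'   variant)
#' @return list with `fold_risks`, `mean_risk`, `level_one` (the n
#'   out-of-fold predictions)
#' @export
cross_validated_risk <- function(spec, dataset, folds, loss = "sqe",
                                 pooled = FALSE) {
  col <- level_one_column(spec, dataset, folds)
  r <- risk_by_fold(loss, dataset$outcome, col, folds, pooled)
  c(r, list(level_one = col, loss = normalize_loss(loss), k = folds$k))
}

level_one_column <- function(spec, dataset, folds) {
  n <- nrow(dataset$genotype)
  stopifnot(length(folds$fold_index) == n)
  col <- numeric(n)
  for (f in seq_len(folds$k)) {
    v <- folds$fold_index == f
    train <- geno_dataset(dataset$genotype[!v, , drop = FALSE],
                          dataset$outcome[!v])
    fit <- tryCatch(fit_learner(spec, train), error = function(e) {
      stop_slgeno(sprintf("learner %s failed on fold %d: %s",
                          spec$name, f, conditionMessage(e)),
                  "slgeno_fit_error")
    })
    col[v] <- predict(fit, dataset$genotype[v, , drop = FALSE])
  }
  col
}

#' Level-one matrix of out-of-fold predictions
#'
#' One column per learner; every entry is produced by a model that
#' never saw that patient's fold. All learners share the same fold
#' assignment, so cross-validated risks are comparable.
#'
#' @param specs named list of [learner_spec()]
#' @param dataset a [geno_dataset()]
#' @param folds a [make_folds()] assignment
#' @return n x L matrix with learner-name columns; the fold assignment
#'   is attached as attribute `"folds"`
#' @export
level_one_matrix <- function(specs, dataset, folds) {
  Z <- vapply(specs, level_one_column, numeric(nrow(dataset$genotype)),
              dataset = dataset, folds = folds)
  dimnames(Z) <- list(rownames(dataset$genotype),
                      vapply(specs, `[[`, "", "name"))
  attr(Z, "folds") <- folds
  Z
}

#' Rank learners by mean cross-validated risk
#'
#' Ascending ranks (1 = best); exact ties (after rounding risks to 10
#' decimal places) share the mean of the positions they occupy, so two
#' learners tied at the top both get rank 1.5.
#'
#' @param mean_risks named numeric vector of risks
#' @return named numeric vector of ranks, summing to L(L+1)/2
#' @export
rank_learners <- function(mean_risks) {
  stopifnot(length(mean_risks) >= 1, all(is.finite(mean_risks)))
  rank(round(mean_risks, 10), ties.method = "average")
}

#' Cross-validated risk table (one k, one loss)
#'
#' The machine twin of one block of the published risk tables: one row
#' per learner with per-fold risks, the mean cross-validated risk and
#' the mean-rank column.
#'
#' @inheritParams level_one_matrix
#' @param loss `"sqe"` or `"one_minus_r"`
#' @param Z optional precomputed [level_one_matrix()] (so several
#'   losses can score the same fits); columns must match `specs`
#' @param pooled score pooled over folds instead of per-fold averaged
#' @return object of class `cv_risk_table`: data.frame with columns
#'   `learner`, `fold_<i>`, `mean_risk`, `rank`; attributes `k`,
#'   `loss`, `level_one`
#' @export
cv_risk_table <- function(specs, dataset, folds, loss = "sqe", Z = NULL,
                          pooled = FALSE) {
  loss <- normalize_loss(loss)
  if (is.null(Z)) Z <- level_one_matrix(specs, dataset, folds)
  names <- vapply(specs, `[[`, "", "name")
  stopifnot(identical(colnames(Z), unname(names)))
  rs <- lapply(seq_along(specs), function(j) {
    risk_by_fold(loss, dataset$outcome, Z[, j], folds, pooled)
  })
  mean_risk <- vapply(rs, `[[`, 0, "mean_risk")
  fold_mat <- do.call(rbind, lapply(rs, `[[`, "fold_risks"))
  tab <- data.frame(learner = unname(names), fold_mat, mean_risk = mean_risk,
                    rank = unname(rank_learners(stats::setNames(mean_risk, names))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[1 + seq_len(ncol(fold_mat))] <- paste0("fold_", seq_len(ncol(fold_mat)))
  structure(tab, k = folds$k, loss = loss, level_one = Z,
            class = c("cv_risk_table", "data.frame"))
}

#' Serialize a CV risk table to CSV
#' @param table a [cv_risk_table()]
#' @param path output CSV path
#' @export
write_cv_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
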