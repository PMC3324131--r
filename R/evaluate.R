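# Full-dataset evaluation: SqE, 1-R (pooled), R^2, per-metric
# mean-ranks, responder classification and accuracy at the two
# published thresholds, and the selected-mutations report.

#' Squared Pearson correlation between observed and predicted outcomes
#'
#' R^2 is defined as the square of the correlation coefficient (not
#' 1 - SSres/SStot), so it is invariant under positive affine
#' transformations of the predictions and satisfies
#' `r_squared = (1 - (1-R))^2` whenever R >= 0. Constant predictions
#' give 0 by convention.
#'
#' @param y observed outcomes (length >= 2)
#' @param pred predictions
#' @return value in \[0, 1\]
#' @export
r_squared <- function(y, pred) {
  stopifnot(length(y) == length(pred))
  if (length(y) < 2) {
    stop_slgeno("r_squared needs at least 2 observations",
                "slgeno_parameter_error")
  }
  if (stats::sd(y) == 0 || stats::sd(pred) == 0) return(0)
  stats::cor(y, pred)^2
}

#' Classify virologic response at a delta VL threshold
#'
#' A patient is a responder when the HIV-1 RNA reduction reaches the
#' threshold, i.e. delta VL <= threshold (equality counts as response;
#' ties are measure-zero for continuous predictions).
#'
#' @param values delta VL vector, log10 copies/mL
#' @param threshold negative cut-off, conventionally -0.5 or -0.6
#' @return logical responder flags
#' @export
classify_response <- function(values, threshold) {
  stopifnot(threshold < 0)
  values <= threshold
}

#' Classification accuracy of predicted response
#'
#' Fraction of patients whose predicted and observed responder status
#' (via [classify_response()]) agree.
#'
#' @param y_obs observed delta VL
#' @param y_pred predicted delta VL
#' @param threshold responder cut-off
#' @return fraction in \[0, 1\]
#' @export
accuracy <- function(y_obs, y_pred, threshold) {
  stopifnot(length(y_obs) == length(y_pred))
  if (!length(y_obs)) {
    stop_slgeno("accuracy of an empty vector is undefined",
                "slgeno_parameter_error")
  }
  mean(classify_response(y_obs, threshold) ==
         classify_response(y_pred, threshold))
}

model_predictions <- function(models, dataset) {
  vapply(models, predict, numeric(nrow(dataset$genotype)),
         newdata = dataset)
}

#' Full-dataset model report
#'
#' For every fitted model: squared error, pooled 1-R and R^2 on the
#' full dataset, each with its mean-rank column (rank 1 = best: lowest
#' SqE and 1-R, highest R^2).
#'
#' @param dataset the [geno_dataset()] the models were fitted on
#' @param models named list of fitted models (each with a `predict`
#'   method)
#' @return object of class `full_model_report` (a data.frame)
#' @export
full_model_report <- function(dataset, models) {
  y <- dataset$outcome
  P <- model_predictions(models, dataset)
  sqe <- apply(P, 2, function(p) risk("sqe", y, p))
  omr <- apply(P, 2, function(p) suppressWarnings(risk("one_minus_r", y, p)))
  r2 <- apply(P, 2, function(p) r_squared(y, p))
  out <- data.frame(
    model = names(models),
    sqe = unname(sqe), sqe_rank = unname(rank_learners(sqe)),
    one_minus_r = unname(omr), one_minus_r_rank = unname(rank_learners(omr)),
    r_squared = unname(r2), r_squared_rank = unname(rank_learners(-r2)),
    stringsAsFactors = FALSE)
  structure(out, class = c("full_model_report", "data.frame"))
}

#' Responder-classification accuracy report
#'
#' Long-format accuracy of every model at every threshold (the
#' bar-chart-ready twin of the published classification figure).
#'
#' @inheritParams full_model_report
#' @param thresholds responder cut-offs (default -0.5 and -0.6)
#' @return data.frame with columns `model`, `threshold`, `accuracy`
#' @export
accuracy_report <- function(dataset, models, thresholds = c(-0.5, -0.6)) {
  y <- dataset$outcome
  P <- model_predictions(models, dataset)
  out <- expand.grid(model = names(models), threshold = thresholds,
                     stringsAsFactors = FALSE)
  out$accuracy <- mapply(function(m, thr) accuracy(y, P[, m], thr),
                         out$model, out$threshold)
  out
}

#' Mutations selected by each fitted model
#'
#' @param models named list of fitted models
#' @return named list of canonical mutation-label vectors (the
#'   [selected_features()] of each model)
#' @export
selected_mutations_report <- function(models) {
  lapply(models, selected_features)
}
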