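# Orchestration: one call produces the machine twins of the published
# risk tables (per k, loss, roster), the full-dataset report, the
# accuracy report, the selected-mutations map and the fitted weights,
# all deterministically from (dataset, config, master seed). Folds are
# computed once per k and shared by every learner and loss, so ranks
# are not perturbed by fold noise.

#' Analysis configuration
#'
#' @param dataset a [geno_dataset()] (alternatively give `dataset_csv`
#'   or `synthetic`)
#' @param dataset_csv path to a dataset CSV in the package dialect
#' @param synthetic a [synthetic_config()] to generate the dataset from
#' @param ks fold counts (default 10, 4, 3, 2 — training fractions
#'   90/75/66/50%)
#' @param losses loss functions (default both `"sqe"` and
#'   `"one_minus_r"`)
#' @param rosters Super Learner rosters (default `"SL5"` and `"SL6"`)
#' @param thresholds responder cut-offs, negative (default -0.5, -0.6)
#' @param seed master seed; folds, stochastic learners and weight
#'   multi-starts are derived from it by a stable hash fan-out
#' @param out_dir output directory (NULL = in-memory result only)
#' @param honest report the Super Learner rows by honest nested CV
#'   instead of the level-one risk of the fitted combination
#' @param learner_args named list of hyperparameter overrides per
#'   learner (e.g. `list(rf = list(n_trees = 100))`)
#' @return object of class `analysis_config`
#' @export
analysis_config <- function(dataset = NULL, dataset_csv = NULL,
                            synthetic = NULL,
                            ks = c(10L, 4L, 3L, 2L),
                            losses = c("sqe", "one_minus_r"),
                            rosters = c("SL5", "SL6"),
                            thresholds = c(-0.5, -0.6),
                            seed = 1L, out_dir = NULL, honest = FALSE,
                            learner_args = list()) {
  if (is.null(dataset) && is.null(dataset_csv) && is.null(synthetic)) {
    stop_slgeno("one of dataset, dataset_csv or synthetic is required",
                "slgeno_parameter_error")
  }
  if (any(thresholds >= 0)) {
    stop_slgeno("responder thresholds must be negative (delta VL reductions)",
                "slgeno_parameter_error")
  }
  if (any(ks < 2)) {
    stop_slgeno("fold counts must be >= 2", "slgeno_parameter_error")
  }
  losses <- vapply(losses, normalize_loss, "")
  rosters <- vapply(rosters, function(r) match.arg(r, names(SL_ROSTERS)), "")
  structure(list(dataset = dataset, dataset_csv = dataset_csv,
                 synthetic = synthetic, ks = as.integer(ks),
                 losses = unname(losses), rosters = unname(rosters),
                 thresholds = thresholds, seed = as.integer(seed),
                 out_dir = out_dir, honest = isTRUE(honest),
                 learner_args = learner_args),
            class = "analysis_config")
}

load_config_dataset <- function(config) {
  if (!is.null(config$dataset)) return(config$dataset)
  if (!is.null(config$dataset_csv)) return(read_dataset(config$dataset_csv))
  generate_jaguar_like(config$synthetic,
                       seed = config$synthetic$seed %||%
                         derive_seed(config$seed, "synthetic"))
}

sl_display <- function(roster) {
  c(SL5 = "Super Learner-5", SL6 = "Super Learner-6")[[roster]]
}

# One CV risk table for a (k, loss, roster) triple: learner rows from
# the shared level-one matrix, plus the Super Learner row.
roster_cv_table <- function(Z, y, folds, loss, roster, specs, seed,
                            honest = FALSE, dataset = NULL,
                            learner_args = list()) {
  names_ <- sl_roster(roster)
  Zr <- Z[, names_, drop = FALSE]
  rs <- lapply(names_, function(nm) risk_by_fold(loss, y, Z[, nm], folds))
  mean_risk <- vapply(rs, `[[`, 0, "mean_risk")
  weights <- fit_sl_weights(Zr, y, loss, seed = derive_seed(seed, "weights", roster))
  if (honest) {
    sl_row <- honest_sl_risk(dataset, roster, folds$k, loss,
                             seed = derive_seed(seed, "honest", roster),
                             outer_k = folds$k,
                             learner_args = learner_args)
    sl_fold <- sl_row$fold_risks
    sl_mean <- sl_row$mean_risk
  } else {
    pred <- drop(Zr %*% weights$weights)
    r <- risk_by_fold(loss, y, pred, folds)
    sl_fold <- r$fold_risks
    sl_mean <- r$mean_risk
  }
  fold_mat <- rbind(do.call(rbind, lapply(rs, `[[`, "fold_risks")), sl_fold)
  all_names <- c(LEARNER_DISPLAY[names_], sl_display(roster))
  means <- c(mean_risk, sl_mean)
  tab <- data.frame(learner = unname(all_names), fold_mat,
                    mean_risk = unname(means),
                    rank = unname(rank_learners(means)),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(tab)[1 + seq_len(ncol(fold_mat))] <-
    paste0("fold_", seq_len(ncol(fold_mat)))
  structure(tab, k = folds$k, loss = loss, roster = roster,
            weights = weights,
            class = c("cv_risk_table", "data.frame"))
}

# Tables-1/2-style wide summary: rank and mean risk per k plus the
# trailing mean-rank column.
summarize_across_k <- function(tables) {
  ks <- vapply(tables, attr, 0L, "k")
  out <- data.frame(learner = tables[[1]]$learner, stringsAsFactors = FALSE)
  rank_cols <- matrix(NA_real_, nrow(out), length(ks))
  for (i in seq_along(tables)) {
    stopifnot(identical(tables[[i]]$learner, out$learner))
    out[[paste0("rank_k", ks[i])]] <- tables[[i]]$rank
    out[[paste0("mean_k", ks[i])]] <- tables[[i]]$mean_risk
    rank_cols[, i] <- tables[[i]]$rank
  }
  out$mean_rank <- rowMeans(rank_cols)
  out
}

#' Run the full Super Learner analysis
#'
#' For every configured fold count the folds are drawn once and shared;
#' the six learners' level-one predictions are computed once and scored
#' under every loss; Super Learner weights are fitted per (k, loss,
#' roster); every model is refitted on the full dataset for the
#' full-model, accuracy and selected-mutations reports. With an output
#' directory set, everything is serialized under `tables/`, `weights/`,
#' `figures_data/` and `meta.json`.
#'
#' @param config an [analysis_config()]
#' @return object of class `analysis_result`
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- config$out_dir
  created <- !is.null(out_dir) && !dir.exists(out_dir)
  run <- function() {
    dataset <- load_config_dataset(config)
    n <- nrow(dataset$genotype)
    if (any(config$ks > n)) {
      stop_slgeno(sprintf("fold count %d exceeds patient count %d",
                          max(config$ks), n), "slgeno_parameter_error")
    }
    seed <- config$seed
    all_learners <- LEARNER_ORDER
    specs <- lapply(all_learners, function(nm) {
      learner_spec(nm, hyper = config$learner_args[[nm]] %||% list(),
                   seed = derive_seed(seed, nm))
    })
    names(specs) <- all_learners
    y <- dataset$outcome

    sl_log("info", "computing level-one matrices")
    folds_by_k <- lapply(config$ks, function(k) {
      make_folds(n, k, derive_seed(seed, "folds", k))
    })
    Z_by_k <- lapply(folds_by_k, function(folds) {
      t0 <- Sys.time()
      Z <- level_one_matrix(specs, dataset, folds)
      sl_log("debug", sprintf("k = %d level-one matrix in %.1fs", folds$k,
                              as.numeric(Sys.time() - t0, units = "secs")))
      Z
    })

    cv_tables <- list()
    weights <- list()
    for (loss in config$losses) {
      for (roster in config$rosters) {
        per_k <- list()
        for (i in seq_along(config$ks)) {
          tab <- roster_cv_table(Z_by_k[[i]], y, folds_by_k[[i]], loss,
                                 roster, specs, seed,
                                 honest = config$honest, dataset = dataset,
                                 learner_args = config$learner_args)
          key <- sprintf("%s_%s_k%d", loss, roster, config$ks[i])
          cv_tables[[key]] <- tab
          weights[[key]] <- attr(tab, "weights")
          per_k[[i]] <- tab
        }
        cv_tables[[paste0("summary_", loss, "_", roster)]] <-
          summarize_across_k(per_k)
      }
    }

    sl_log("info", "refitting on the full dataset")
    full_fits <- lapply(specs, fit_learner, dataset = dataset)
    names(full_fits) <- unname(LEARNER_DISPLAY[all_learners])
    models <- full_fits
    for (roster in config$rosters) {
      key0 <- sprintf("%s_%s_k%d", config$losses[1], roster, config$ks[1])
      sl <- structure(list(roster = roster, weights = weights[[key0]],
                           full_fits = full_fits[unname(LEARNER_DISPLAY[sl_roster(roster)])],
                           folds = folds_by_k[[1]], loss = config$losses[1],
                           seed = seed),
                      class = "super_learner")
      names(sl$full_fits) <- sl_roster(roster)
      models[[sl_display(roster)]] <- sl
    }

    full_report <- full_model_report(dataset, models)
    acc_report <- accuracy_report(dataset, models, config$thresholds)
    selected <- selected_mutations_report(models)

    result <- structure(
      list(dataset = dataset, cv_tables = cv_tables, weights = weights,
           full_model_report = full_report, accuracy_report = acc_report,
           selected_mutations = selected, models = models,
           config = config,
           meta = list(seed = seed, ks = config$ks, losses = config$losses,
                       rosters = config$rosters,
                       thresholds = config$thresholds,
                       honest = config$honest,
                       n_patients = n,
                       mutation_labels = colnames(dataset$genotype),
                       package_version = as.character(utils::packageVersion("slgeno")),
                       r_version = R.version.string,
                       timestamp = format(Sys.time(), tz = "UTC"))),
      class = "analysis_result")
    if (!is.null(out_dir)) write_analysis_result(result, out_dir)
    result
  }
  tryCatch(run(), error = function(e) {
    if (created && dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
    stop(e)
  })
}

#' Serialize an analysis result to a run directory
#' @param result an `analysis_result`
#' @param out_dir directory (created if needed) receiving `tables/`,
#'   `weights/`, `figures_data/` and `meta.json`
#' @export
write_analysis_result <- function(result, out_dir) {
  for (d in c("", "tables", "weights", "figures_data")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  for (key in names(result$cv_tables)) {
    utils::write.csv(as.data.frame(result$cv_tables[[key]]),
                     file.path(out_dir, "tables", paste0(key, ".csv")),
                     row.names = FALSE)
  }
  for (key in names(result$weights)) {
    write_sl_weights(result$weights[[key]],
                     file.path(out_dir, "weights", paste0(key, ".json")),
                     seed = result$meta$seed)
  }
  utils::write.csv(as.data.frame(result$full_model_report),
                   file.path(out_dir, "tables", "full_model_report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$accuracy_report,
                   file.path(out_dir, "figures_data", "accuracy.csv"),
                   row.names = FALSE)
  sel <- result$selected_mutations
  sel_long <- data.frame(
    model = rep(names(sel), lengths(sel)),
    mutation = unlist(sel, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.csv(sel_long,
                   file.path(out_dir, "figures_data", "selected_mutations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("<analysis_result> n = %d, k in {%s}, losses {%s}, rosters {%s}\n",
              x$meta$n_patients, paste(x$meta$ks, collapse = ", "),
              paste(x$meta$losses, collapse = ", "),
              paste(x$meta$rosters, collapse = ", ")))
  cat("\nFull-dataset report:\n")
  print(as.data.frame(x$full_model_report), digits = 3)
  invisible(x)
}
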