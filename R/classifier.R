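#' Fuse per-minute feature blocks
#'
#' Concatenates, per minute, the semantic vector `s_t` and the acoustic
#' MFCC vector `C_t` — and, only in `"paper_faithful"` mode, the binary
#' event record `e_t` as a trailing column. Column order is (s, C\[, e\])
#' and stable across runs.
#'
#' The event record is the prediction target: feeding it back in as a
#' feature leaks the label, so `"inference_safe"` (the default) excludes it
#' and `"paper_faithful"` exists only to reproduce that literal fusion —
#' it emits a warning whenever used.
#'
#' @param semantic_matrix `T x d_s` matrix from [encode_night].
#' @param mfcc_matrix `T x L` matrix from [minute_mfcc].
#' @param event_record Length-`T` binary record (required in
#'   `paper_faithful` mode).
#' @param mode `"inference_safe"` or `"paper_faithful"`.
#' @return `T x (d_s + L [+ 1])` feature matrix.
#' @export
fuse <- function(semantic_matrix, mfcc_matrix, event_record = NULL,
                 mode = c("inference_safe", "paper_faithful")) {
  mode <- match.arg(mode)
  if (nrow(semantic_matrix) != nrow(mfcc_matrix))
    stop("minute count mismatch: semantic matrix has ",
         nrow(semantic_matrix), " rows, MFCC matrix has ",
         nrow(mfcc_matrix), call. = FALSE)
  out <- cbind(semantic_matrix, mfcc_matrix)
  if (mode == "paper_faithful") {
    if (is.null(event_record))
      stop("paper_faithful fusion requires the event record", call. = FALSE)
    if (length(event_record) != nrow(out))
      stop("minute count mismatch: event record has ", length(event_record),
           " entries, feature matrices have ", nrow(out), " rows",
           call. = FALSE)
    warning("paper_faithful fusion includes the event label e_t as a ",
            "feature; predictions from it are circular", call. = FALSE)
    out <- cbind(out, e = as.integer(event_record))
  }
  out
}

#' Train the per-minute apnea-event classifier
#'
#' Fits a gradient boosted tree ensemble minimizing the regularized
#' objective `sum_i l(y_i, yhat_i) + sum_k Omega(f_k)` with binary logistic
#' loss, using the tuned defaults of [run_config] (learning rate 0.3, max
#' depth 9, subsample 0.6, L2 10, L1 0.1, column subsample 0.5, gamma 0.2).
#' Training is single-threaded and seeded, hence reproducible; the
#' per-round training log-loss is recorded.
#'
#' @param features Numeric feature matrix (finite), one row per minute,
#'   pooled across training nights.
#' @param labels Binary 0/1 vector (both classes must be present).
#' @param cfg A [run_config] supplying the boosting hyperparameters.
#' @return A `trained_event_model`: the fitted booster plus config, feature
#'   names, training log, and a fingerprint of the training set.
#' @export
train_event_classifier <- function(features, labels, cfg = run_config()) {
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class; need both 0 and 1",
         call. = FALSE)
  if (length(labels) != nrow(features))
    stop("labels length must match feature rows", call. = FALSE)
  bad <- colnames(features)[!apply(is.finite(features), 2L, all)]
  if (length(bad))
    stop("non-finite feature values in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  dtrain <- xgboost::xgb.DMatrix(features, label = as.numeric(labels))
  booster <- xgboost::xgb.train(
    params = list(objective = cfg$objective, eta = cfg$learning_rate,
                  max_depth = cfg$max_depth, subsample = cfg$subsample,
                  lambda = cfg$reg_lambda, alpha = cfg$reg_alpha,
                  colsample_bytree = cfg$colsample_bytree, gamma = cfg$gamma,
                  nthread = 1L, seed = cfg$random_seed),
    data = dtrain, nrounds = cfg$n_rounds,
    evals = list(train = dtrain), verbose = 0)
  structure(list(booster = booster,
                 feature_names = colnames(features),
                 config = cfg,
                 training_log = as.data.frame(
                   attr(booster, "evaluation_log")),
                 fingerprint = c(n = nrow(features), p = ncol(features),
                                 positives = sum(labels == 1))),
            class = "trained_event_model")
}

#' @export
print.trained_event_model <- function(x, ...) {
  cat(sprintf("<trained_event_model> %d features, %d rounds, %d/%d positive\n",
              length(x$feature_names), nrow(x$training_log),
              x$fingerprint[["positives"]], x$fingerprint[["n"]]))
  invisible(x)
}

#' Predict per-minute apnea events
#'
#' @param model A [trained_event_model].
#' @param features Feature matrix whose columns match training exactly.
#' @param threshold Decision threshold on the score (default 0.5).
#' @return List with `scores` (in \[0, 1\]) and `labels`
#'   (`score >= threshold`, 0/1).
#' @export
predict_minutes <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "trained_event_model"))
  if (!identical(colnames(features), model$feature_names))
    stop("feature columns do not match training columns\n  expected: ",
         paste(model$feature_names, collapse = ", "), "\n  got: ",
         paste(colnames(features), collapse = ", "), call. = FALSE)
  scores <- stats::predict(model$booster, xgboost::xgb.DMatrix(features))
  list(scores = scores, labels = as.integer(scores >= threshold))
}

#' Night-grouped cross-validation over a hyperparameter grid
#'
#' Evaluates each candidate configuration by k-fold cross-validation with
#' folds grouped by night: all minutes of one night stay in the same fold,
#' so no within-night leakage inflates validation scores. The best
#' configuration by mean validation AUC is returned along with the full
#' per-fold results.
#'
#' @param features Pooled per-minute feature matrix.
#' @param labels Binary labels.
#' @param nights Night identifier per row (grouping variable).
#' @param grid List of [run_config] candidates (default: one, the package
#'   defaults).
#' @param k Number of folds (`>= 2`, at most the number of distinct nights).
#' @param seed Seed for the fold assignment shuffle.
#' @return List with `best_config`, `best_auc`, and `results` (data.frame:
#'   config index, fold, auc).
#' @export
cross_validate <- function(features, labels, nights, grid = list(run_config()),
                           k = 5L, seed = 1L) {
  ids <- unique(nights)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (length(ids) < k)
    stop("fewer nights (", length(ids), ") than folds (", k, ")",
         call. = FALSE)
  fold_of <- with_local_rng(seed,
    stats::setNames(sample(rep(seq_len(k), length.out = length(ids))), ids))
  rows <- list()
  for (ci in seq_along(grid)) {
    for (f in seq_len(k)) {
      hold <- nights %in% ids[fold_of[as.character(ids)] == f]
      model <- train_event_classifier(features[!hold, , drop = FALSE],
                                      labels[!hold], grid[[ci]])
      sc <- predict_minutes(model, features[hold, , drop = FALSE])$scores
      auc <- if (length(unique(labels[hold])) < 2L) NA_real_
             else roc_auc(labels[hold], sc)$auc
      rows[[length(rows) + 1L]] <- data.frame(config = ci, fold = f,
                                              auc = auc)
    }
  }
  results <- do.call(rbind, rows)
  mean_auc <- tapply(results$auc, results$config, mean, na.rm = TRUE)
  best <- as.integer(names(which.max(mean_auc)))
  list(best_config = grid[[best]], best_auc = unname(mean_auc[best]),
       results = results, fold_of = fold_of)
}
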