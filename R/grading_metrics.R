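#' Count apnea events in a per-minute record
#'
#' Two counting conventions over a binary minute record:
#' `"positive_minutes"` (default) counts every apnea-positive minute as one
#' event — consistent with a per-minute classifier whose positives are
#' summed over the night; `"contiguous_runs"` counts maximal runs of
#' consecutive positive minutes, the clinically conventional alternative.
#'
#' @param e Binary 0/1 vector (predicted or true event record).
#' @param mode `"positive_minutes"` or `"contiguous_runs"`.
#' @return Integer event count N.
#' @export
count_events <- function(e, mode = c("positive_minutes", "contiguous_runs")) {
  mode <- match.arg(mode)
  if (!all(e %in% c(0, 1))) stop("event record must be binary", call. = FALSE)
  e <- as.integer(e)
  if (mode == "positive_minutes") sum(e)
  else sum(diff(c(0L, e)) == 1L)
}

#' Apnea-hypopnea index
#'
#' `AHI = N / t`: the night's event count divided by sleep duration in
#' hours.
#'
#' @param n_events Event count N (`>= 0`).
#' @param sleep_hours Sleep duration t in hours (`> 0`).
#' @param counting_mode Convention used to obtain N (recorded, not applied).
#' @return An object of class `ahi_result` with `n_events`, `sleep_hours`,
#'   `ahi`, `counting_mode`, and the derived `severity` (see
#'   [grade_severity]).
#' @examples
#' compute_ahi(44, 8)$ahi    # 5.5
#' @export
compute_ahi <- function(n_events, sleep_hours,
                        counting_mode = "positive_minutes") {
  if (sleep_hours <= 0) stop("sleep_hours must be positive", call. = FALSE)
  if (n_events < 0) stop("n_events must be nonnegative", call. = FALSE)
  ahi <- n_events / sleep_hours
  structure(list(n_events = n_events, sleep_hours = sleep_hours, ahi = ahi,
                 counting_mode = counting_mode,
                 severity = grade_severity(ahi)),
            class = "ahi_result")
}

#' @export
print.ahi_result <- function(x, ...) {
  cat(sprintf("<ahi_result> N=%g over %.2f h: AHI=%.3f -> %s (%d)\n",
              x$n_events, x$sleep_hours, x$ahi,
              names(x$severity), x$severity))
  invisible(x)
}

#' Four-class OSAHS severity from AHI
#'
#' The standard clinical bins: normal / simple snoring (AHI < 5), mild
#' (5 <= AHI < 15), moderate (15 <= AHI < 30), severe (AHI >= 30), encoded
#' as integers 0–3. Boundaries belong to the upper class. Vectorized.
#'
#' @param ahi Nonnegative AHI value(s), events per hour.
#' @param thresholds The three increasing cut points (default `c(5, 15, 30)`).
#' @return Named integer vector in 0..3; names are the class names.
#' @examples
#' grade_severity(c(2.125, 5.5, 18, 48.625))
#' @export
grade_severity <- function(ahi, thresholds = c(5, 15, 30)) {
  if (any(ahi < 0)) stop("AHI must be nonnegative", call. = FALSE)
  lab <- findInterval(ahi, thresholds)
  names(lab) <- c("normal", "mild", "moderate", "severe")[lab + 1L]
  lab
}

#' Binary classification metrics
#'
#' Confusion counts and the derived metrics, computed exactly from their
#' definitions: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 the
#' harmonic mean of the two, accuracy `(TP+TN)/n`, specificity
#' `TN/(TN+FP)`. A zero denominator yields 0 with a warning (never `NaN` in
#' reports).
#'
#' @param y_true,y_pred Equal-length binary 0/1 vectors.
#' @return A list of class `eval_report` with counts and metrics.
#' @export
binary_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 n = length(y_true),
                 accuracy = (tp + tn) / length(y_true),
                 precision = precision, recall = recall, f1 = f1,
                 specificity = safe_div(tn, tn + fp, "specificity")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n=%d TP=%d FP=%d FN=%d TN=%d\n",
                     "  acc=%.3f prec=%.3f rec=%.3f F1=%.3f spec=%.3f\n"),
              x$n, x$TP, x$FP, x$FN, x$TN, x$accuracy, x$precision,
              x$recall, x$f1, x$specificity))
  invisible(x)
}

#' Regression metrics for AHI estimation
#'
#' `MAE = mean |y - yhat|`, `MSE = mean (y - yhat)^2`, and the coefficient
#' of determination `R^2 = 1 - sum (y - yhat)^2 / sum (y - ybar)^2`. With
#' `paper_faithful_r2 = TRUE` the denominator is computed as
#' `sum (ybar - yhat)^2` instead (a nonstandard variant retained for
#' comparability). Zero variance in `y_true` makes the standard `R^2`
#' undefined; 0 is returned with a warning.
#'
#' @param y_true,y_pred Equal-length numeric vectors (`n >= 2` for `R^2`).
#' @param paper_faithful_r2 Use the nonstandard denominator.
#' @return List with `mae`, `mse`, `r2`.
#' @export
regression_metrics <- function(y_true, y_pred, paper_faithful_r2 = FALSE) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  res <- y_true - y_pred
  denom <- if (paper_faithful_r2) sum((mean(y_true) - y_pred)^2)
           else sum((y_true - mean(y_true))^2)
  r2 <- if (denom == 0) {
    warning("R^2 undefined (zero denominator); reporting 0", call. = FALSE)
    0
  } else 1 - sum(res^2) / denom
  list(mae = mean(abs(res)), mse = mean(res^2), r2 = r2)
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the unique scores, recording
#' (FPR, TPR) at each, and integrates by the trapezoidal rule. Tied scores
#' are grouped, so the result equals the rank statistic: the probability
#' that a random positive outscores a random negative, ties counted half.
#'
#' @param y_true Binary 0/1 vector with both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return List with `auc` and `roc_points` (data.frame `fpr`, `tpr`,
#'   monotone non-decreasing in both coordinates, from (0,0) to (1,1)).
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    stop("y_true and scores must have equal length", call. = FALSE)
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC requires both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  grp_last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- cumsum(y == 1)[grp_last]
  fp <- cumsum(y == 0)[grp_last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, roc_points = data.frame(fpr = fpr, tpr = tpr))
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean drop in AUC when one feature column
#' is randomly permuted, averaged over `n_repeats` seeded permutations.
#' Features whose scrambling does not hurt discrimination score near zero.
#'
#' @param model A [trained_event_model].
#' @param features Feature matrix matching the model's training columns.
#' @param labels Binary 0/1 labels.
#' @param n_repeats Permutations per feature (`>= 1`, default 5).
#' @param seed Integer seed.
#' @return data.frame (`feature`, `auc_drop`) sorted by decreasing drop.
#' @export
feature_importance <- function(model, features, labels, n_repeats = 5L,
                               seed = 1L) {
  stopifnot(inherits(model, "trained_event_model"))
  base <- roc_auc(labels, predict_minutes(model, features)$scores)$auc
  drops <- with_local_rng(seed, {
    vapply(seq_len(ncol(features)), function(j) {
      mean(vapply(seq_len(n_repeats), function(r) {
        perm <- features
        perm[, j] <- perm[sample(nrow(perm)), j]
        base - roc_auc(labels, predict_minutes(model, perm)$scores)$auc
      }, numeric(1)))
    }, numeric(1))
  })
  out <- data.frame(feature = colnames(features), auc_drop = drops)
  out[order(-out$auc_drop), , drop = FALSE]
}
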