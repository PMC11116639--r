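#' Apnea event annotations
#'
#' An `event_list` holds validated, sorted, merged apnea-event intervals for
#' one night. Times are seconds from recording start; intervals are
#' half-open `[start_s, end_s)`.
#'
#' @param events A data.frame with columns `start_s`, `end_s`, `kind`
#'   (`"apnea"` or `"other"`).
#' @param night_duration_s Night length in seconds.
#' @param merge Merge overlapping (or touching) apnea intervals into one.
#' @return An object of class `event_list`.
#' @export
event_list <- function(events, night_duration_s, merge = TRUE) {
  stopifnot(is.data.frame(events))
  need <- c("start_s", "end_s", "kind")
  if (!all(need %in% names(events)))
    stop("events must have columns start_s, end_s, kind", call. = FALSE)
  events$start_s <- as.numeric(events$start_s)
  events$end_s <- as.numeric(events$end_s)
  events$kind <- as.character(events$kind)
  if (anyNA(events$start_s) || anyNA(events$end_s))
    stop("unparseable start_s/end_s value in annotations", call. = FALSE)
  bad <- which(events$end_s <= events$start_s)
  if (length(bad))
    stop("invalid event interval (end_s <= start_s) at row ", bad[1],
         call. = FALSE)
  if (any(events$start_s < 0))
    stop("event start before recording start", call. = FALSE)
  if (any(events$end_s > night_duration_s + 1e-9))
    stop("event extends past recording end (", night_duration_s, " s)",
         call. = FALSE)
  events <- events[order(events$start_s, events$end_s), , drop = FALSE]
  if (merge) events <- merge_events(events)
  rownames(events) <- NULL
  structure(list(events = events, night_duration_s = night_duration_s),
            class = "event_list")
}

# Merge overlapping or touching intervals, per kind. Half-open convention:
# [10,50) and [50,80) union to the contiguous [10,80).
merge_events <- function(events) {
  if (nrow(events) == 0L) return(events)
  parts <- split(events, events$kind)
  merged <- lapply(parts, function(df) {
    df <- df[order(df$start_s, df$end_s), , drop = FALSE]
    out_s <- df$start_s[1]; out_e <- df$end_s[1]
    keep <- list()
    for (i in seq_len(nrow(df))[-1]) {
      if (df$start_s[i] <= out_e[length(out_e)]) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], df$end_s[i])
      } else {
        out_s <- c(out_s, df$start_s[i]); out_e <- c(out_e, df$end_s[i])
      }
    }
    data.frame(start_s = out_s, end_s = out_e, kind = df$kind[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out[order(out$start_s, out$end_s), , drop = FALSE]
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d events over %.0f s\n",
              nrow(x$events), x$night_duration_s))
  invisible(x)
}

#' Read an annotation table
#'
#' Annotations are tab-separated text with a header naming the columns
#' `start_s`, `end_s`, `kind`, one event per row; `#` starts a comment.
#' Overlapping apnea intervals are merged on read.
#'
#' @param path Path to a TSV annotation file.
#' @param night_duration_s Night length in seconds. If `NULL`, a
#'   `# night_duration_s: <x>` comment line in the file is used; failing
#'   that, the last event end.
#' @return An [event_list].
#' @export
read_annotations <- function(path, night_duration_s = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  if (is.null(night_duration_s)) {
    hdr <- grep("^#\\s*night_duration_s:", readLines(path, warn = FALSE),
                value = TRUE)
    if (length(hdr))
      night_duration_s <- as.numeric(sub("^#\\s*night_duration_s:\\s*", "",
                                         hdr[1]))
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (is.null(night_duration_s)) {
    night_duration_s <- if (nrow(df)) max(as.numeric(df$end_s)) else 0
  }
  event_list(df, night_duration_s)
}

#' Write an annotation table
#'
#' @param el An [event_list].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(el, path) {
  stopifnot(inherits(el, "event_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# night_duration_s: %.6f", el$night_duration_s), con)
  utils::write.table(el$events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Persist and load labeled feature matrices
#'
#' Feature matrices (per-minute MFCC or semantic matrices) round-trip
#' losslessly through either a delimited-text format (`.tsv`, values at full
#' double precision via 17 significant digits) or R's native binary
#' serialization (`.rds`). `NaN` entries are preserved.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Destination ending in `.tsv` or `.rds`.
#' @return `path` invisibly (write); the matrix (read).
#' @export
write_feature_matrix <- function(m, path) {
  if (!is.matrix(m) || !is.numeric(m) || length(m) == 0L)
    stop("feature matrix must be a nonempty numeric matrix", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  if (grepl("\\.rds$", path)) {
    saveRDS(m, path)
  } else {
    df <- data.frame(row = rownames(m),
                     apply(m, 2L, function(v) sprintf("%.17g", v)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("feature matrix file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.rds$", path)) {
    m <- readRDS(path)
    if (!is.matrix(m) || !is.numeric(m))
      stop("format error: ", path, " does not hold a numeric matrix",
           call. = FALSE)
    return(m)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"row" %in% names(df) || ncol(df) < 2L)
    stop("format error: expected a 'row' label column plus value columns in ",
         path, call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$row)
  m
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default. Classifier
#' defaults are the tuned boosted-tree settings (learning rate 0.3,
#' max depth 9, subsample 0.6, L2 10, L1 0.1, column subsample 0.5,
#' gamma 0.2). Acoustic defaults are standard speech-processing choices:
#' 25 ms frames, 10 ms hop, Hamming window, 26 mel filters, 13 cepstral
#' coefficients.
#'
#' @param ... Named overrides of any default field.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    frame_length_s = 0.025,
    hop_length_s = 0.010,
    window_name = "hamming",
    n_fft = NULL,              # NULL: smallest power of two >= frame length
    n_mel_filters = 26L,
    n_mfcc = 13L,
    fmin_hz = 0,
    fmax_hz = NULL,            # NULL: Nyquist
    log_floor = 1e-10,
    minute_aggregation = "mean",   # mean | median | mean_sd
    encoder_backend = "deterministic_fallback",
    encoder_dim = 8L,
    encoder_precision = 4L,
    encoder_pooling = "first_token",
    fusion_mode = "inference_safe",  # or "paper_faithful" (leaks the label)
    label_rule = "event_duration",   # or "within_minute_overlap"
    min_event_duration_s = 30,
    counting_mode = "positive_minutes",  # or "contiguous_runs"
    decision_threshold = 0.5,
    learning_rate = 0.3,
    max_depth = 9L,
    subsample = 0.6,
    reg_lambda = 10,
    reg_alpha = 0.1,
    colsample_bytree = 0.5,
    gamma = 0.2,
    n_rounds = 100L,
    objective = "binary:logistic",
    train_fraction = 0.8,
    severity_thresholds = c(5, 15, 30),
    random_seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_run_config(structure(cfg, class = "run_config"))
}

validate_run_config <- function(cfg) {
  pos <- c("frame_length_s", "hop_length_s", "n_mel_filters", "n_mfcc",
           "encoder_dim", "learning_rate", "max_depth", "subsample",
           "colsample_bytree", "n_rounds", "min_event_duration_s")
  for (f in pos)
    if (cfg[[f]] <= 0) stop("config field ", f, " must be positive",
                            call. = FALSE)
  if (cfg$hop_length_s > cfg$frame_length_s)
    stop("hop_length_s must not exceed frame_length_s", call. = FALSE)
  if (cfg$n_mfcc > cfg$n_mel_filters)
    stop("n_mfcc must not exceed n_mel_filters", call. = FALSE)
  if (!is.null(cfg$fmax_hz) && cfg$fmin_hz >= cfg$fmax_hz)
    stop("fmin_hz must be below fmax_hz", call. = FALSE)
  if (!identical(sort(cfg$severity_thresholds), cfg$severity_thresholds) ||
      length(cfg$severity_thresholds) != 3L)
    stop("severity_thresholds must be three increasing AHI cut points",
         call. = FALSE)
  cfg
}

#' Write / read a run configuration as YAML
#'
#' Every run writes its resolved configuration next to its outputs so that
#' the run can be re-executed bit-identically.
#'
#' @param cfg A [run_config].
#' @param path Destination / source `.yaml` path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}
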