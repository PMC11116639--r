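#' Per-minute binary event record
#'
#' Converts annotated apnea intervals into the per-minute binary record
#' `E = (e_1, ..., e_T)`, `T = ceil(night_duration_s / 60)`, minute `t`
#' covering the half-open window `[60(t-1), 60t)` seconds. Only events of
#' kind `"apnea"` contribute. Two readings of the 30-second rule are
#' implemented:
#'
#' * `"event_duration"` (default): `e_t = 1` iff some apnea event whose
#'   total duration is at least `min_duration_s` overlaps minute `t`. An
#'   80-s event therefore marks every minute it touches.
#' * `"within_minute_overlap"`: `e_t = 1` iff the total apnea time falling
#'   inside minute `t` is at least `min_duration_s`.
#'
#' The first is the default because the rule is stated in terms of the
#' event's duration, and the overlap reading silently drops 30–59 s events
#' that straddle a minute boundary.
#'
#' @param el An [event_list] (validated, merged).
#' @param rule `"event_duration"` or `"within_minute_overlap"`.
#' @param min_duration_s Duration threshold in seconds (default 30,
#'   inclusive: exactly 30 s counts).
#' @return Integer vector of 0/1 labels of class `event_record`, with
#'   attribute `rule`.
#' @export
label_minutes <- function(el, rule = c("event_duration",
                                       "within_minute_overlap"),
                          min_duration_s = 30) {
  stopifnot(inherits(el, "event_list"))
  rule <- match.arg(rule)
  n_min <- as.integer(ceiling(el$night_duration_s / 60))
  e <- integer(n_min)
  ev <- el$events[el$events$kind == "apnea", , drop = FALSE]
  if (nrow(ev)) {
    if (any(ev$end_s > el$night_duration_s + 1e-9))
      stop("event outside night bounds", call. = FALSE)
    if (rule == "event_duration") {
      long <- ev[ev$end_s - ev$start_s >= min_duration_s, , drop = FALSE]
      for (i in seq_len(nrow(long))) {
        t1 <- floor(long$start_s[i] / 60) + 1
        t2 <- ceiling(long$end_s[i] / 60)
        e[t1:t2] <- 1L
      }
    } else {
      for (t in seq_len(n_min)) {
        lo <- 60 * (t - 1); hi <- 60 * t
        ov <- pmin(ev$end_s, hi) - pmax(ev$start_s, lo)
        if (sum(pmax(0, ov)) >= min_duration_s) e[t] <- 1L
      }
    }
  }
  structure(e, class = "event_record", rule = rule)
}

#' Event record table round trip
#'
#' Persists a per-minute binary record as a two-column `(minute, label)`
#' table; the TSV header comment names the labeling rule used.
#'
#' @param e An `event_record` (or plain 0/1 vector).
#' @param path Optional TSV path; if `NULL`, the data.frame is returned.
#' @return The `(minute, label)` data.frame (written to `path` if given).
#' @export
event_record_to_table <- function(e, path = NULL) {
  if (!all(e %in% c(0L, 1L)))
    stop("event record must be binary 0/1", call. = FALSE)
  df <- data.frame(minute = seq_along(e), label = as.integer(e))
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# rule: %s", attr(e, "rule") %||% "unknown"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' @rdname event_record_to_table
#' @param x A `(minute, label)` data.frame or a TSV path.
#' @export
table_to_event_record <- function(x) {
  if (is.character(x)) x <- utils::read.delim(x, comment.char = "#")
  if (!all(c("minute", "label") %in% names(x)))
    stop("expected columns minute, label", call. = FALSE)
  lab <- x$label[order(x$minute)]
  if (!all(lab %in% c(0, 1)))
    stop("non-binary label value in event record table", call. = FALSE)
  structure(as.integer(lab), class = "event_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
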