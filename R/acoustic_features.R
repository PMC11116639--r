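#' Frame and window a recording
#'
#' Slices the waveform into overlapping frames and multiplies each frame by
#' an analysis window. Frame count is
#' `floor((n_samples - frame_length) / hop_length) + 1`; a trailing stretch
#' shorter than one frame is dropped.
#'
#' @param rec An [audio_recording].
#' @param frame_length Frame size in samples.
#' @param hop_length Hop between consecutive frame starts, in samples.
#' @param window_name One of `"hamming"`, `"hann"`, `"rect"`.
#' @return A `frame_length x n_frames` numeric matrix of windowed frames;
#'   attribute `frame_starts` holds each frame's 0-based start sample.
#' @export
frame_and_window <- function(rec, frame_length, hop_length,
                             window_name = "hamming") {
  stopifnot(inherits(rec, "audio_recording"))
  frame_length <- as.integer(frame_length)
  hop_length <- as.integer(hop_length)
  if (hop_length <= 0L || hop_length > frame_length)
    stop("require 0 < hop_length <= frame_length", call. = FALSE)
  if (rec$n_samples < frame_length)
    stop("recording too short: ", rec$n_samples, " samples < one frame of ",
         frame_length, call. = FALSE)
  n_frames <- (rec$n_samples - frame_length) %/% hop_length + 1L
  starts <- (seq_len(n_frames) - 1L) * hop_length
  idx <- outer(seq_len(frame_length), starts, `+`)
  frames <- matrix(rec$samples[idx], nrow = frame_length)
  w <- analysis_window(window_name, frame_length)
  frames <- frames * w
  attr(frames, "frame_starts") <- starts
  frames
}

#' Analysis window
#'
#' @param name `"hamming"`, `"hann"`, or `"rect"`.
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @export
analysis_window <- function(name, n) {
  n <- as.integer(n)
  k <- seq_len(n) - 1L
  switch(match.arg(name, c("hamming", "hann", "rect")),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1L)),
         hann    = 0.5 * (1 - cos(2 * pi * k / (n - 1L))),
         rect    = rep(1, n))
}

#' One-sided power spectrum of a frame
#'
#' Computes the discrete Fourier transform
#' `X(k) = sum_n x(n) exp(-i 2 pi n k / n_fft)` of a (windowed, zero-padded)
#' frame and returns `|X(k)|^2` for the one-sided bins `k = 0 .. n_fft/2`.
#'
#' @param frame Numeric vector, length at most `n_fft` (zero-padded up).
#' @param n_fft Transform size; must be a positive power of two (the fast
#'   transform requirement).
#' @return Numeric vector of `n_fft/2 + 1` nonnegative power values with
#'   attributes `n_fft`.
#' @export
power_spectrum <- function(frame, n_fft) {
  check_n_fft(n_fft)
  if (length(frame) > n_fft)
    stop("frame longer than n_fft (", length(frame), " > ", n_fft, ")",
         call. = FALSE)
  padded <- c(frame, numeric(n_fft - length(frame)))
  X <- stats::fft(padded)
  p <- Mod(X[seq_len(n_fft %/% 2L + 1L)])^2
  attr(p, "n_fft") <- n_fft
  p
}

check_n_fft <- function(n_fft) {
  if (length(n_fft) != 1L || n_fft < 1 || bitwAnd(as.integer(n_fft),
                                                  as.integer(n_fft) - 1L) != 0L)
    stop("n_fft must be a positive power of two, got ", n_fft, call. = FALSE)
  invisible(n_fft)
}

# Vectorized power spectra for a frame matrix (frames in columns).
power_spectra <- function(frames, n_fft) {
  check_n_fft(n_fft)
  if (nrow(frames) > n_fft) stop("frame longer than n_fft", call. = FALSE)
  if (nrow(frames) < n_fft)
    frames <- rbind(frames, matrix(0, n_fft - nrow(frames), ncol(frames)))
  X <- stats::mvfft(frames)
  Mod(X[seq_len(n_fft %/% 2L + 1L), , drop = FALSE])^2
}

#' Mel scale conversion
#'
#' The perceptual mel frequency mapping `m = 2595 log10(1 + f/700)` and its
#' inverse — a strictly increasing bijection on nonnegative frequencies.
#'
#' @param f_hz Frequency in Hz (vectorized, `>= 0`).
#' @param mel Mel value (vectorized, `>= 0`).
#' @return Converted values.
#' @export
hz_to_mel <- function(f_hz) {
  if (any(f_hz < 0)) stop("frequency must be nonnegative", call. = FALSE)
  2595 * log10(1 + f_hz / 700)
}

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(mel) {
  if (any(mel < 0)) stop("mel value must be nonnegative", call. = FALSE)
  700 * (10^(mel / 2595) - 1)
}

#' Build a triangular mel filter bank
#'
#' Places `n_filters + 2` apex/edge points equally spaced on the mel scale
#' between `fmin` and `fmax`, and builds one triangular response per filter
#' over the one-sided FFT bin frequencies. Adjacent filters overlap; each
#' row is unimodal with weights in \[0, 1\].
#'
#' @param n_filters Number of mel filters M (`>= 2`).
#' @param sample_rate Sampling rate in Hz.
#' @param n_fft FFT size the bank will be applied to.
#' @param fmin,fmax Passband edges in Hz; `fmax <= sample_rate / 2`.
#' @return An `n_filters x (n_fft/2 + 1)` weight matrix with attributes
#'   `center_freqs_hz`, `n_fft`, `sample_rate`.
#' @export
build_mel_filterbank <- function(n_filters, sample_rate, n_fft,
                                 fmin = 0, fmax = sample_rate / 2) {
  if (n_filters < 2L) stop("need at least 2 mel filters", call. = FALSE)
  if (fmin >= fmax) stop("fmin must be below fmax", call. = FALSE)
  if (fmax > sample_rate / 2 + 1e-9)
    stop("fmax exceeds the Nyquist frequency", call. = FALSE)
  check_n_fft(n_fft)
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  w <- matrix(0, n_filters, n_bins)
  for (m in seq_len(n_filters)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    w[m, ] <- pmax(0, pmin(up, down))
  }
  attr(w, "center_freqs_hz") <- hz_pts[2L:(n_filters + 1L)]
  attr(w, "n_fft") <- n_fft
  attr(w, "sample_rate") <- sample_rate
  w
}

#' Mel-filtered log energies
#'
#' Applies the filter bank to a one-sided power spectrum:
#' `S_m = sum_k |X(k)|^2 H_m(k)`, then `M_m = log(S_m + eps)` with a small
#' floor `eps` guarding `log(0)`. Natural logarithm.
#'
#' @param ps One-sided power spectrum from [power_spectrum].
#' @param bank Filter bank from [build_mel_filterbank] (same `n_fft`).
#' @param log_floor The additive floor `eps` (default `1e-10`).
#' @return List with `S` (filter energies) and `M_log` (log energies).
#' @export
mel_log_energies <- function(ps, bank, log_floor = 1e-10) {
  if (length(ps) != ncol(bank))
    stop("power spectrum length ", length(ps), " does not match filter bank (",
         ncol(bank), " bins)", call. = FALSE)
  S <- as.numeric(bank %*% ps)
  list(S = S, M_log = log(S + log_floor))
}

#' Cepstral coefficients from mel log energies
#'
#' The final MFCC step: `C_l = sum_{m=1}^{M} M_m cos(pi * l * (m - 0.5) / M)`
#' for `l = 1 .. n_coef` — a type-II discrete cosine transform without
#' orthonormal scaling, starting at the first cosine term (no `C_0` energy
#' term).
#'
#' @param m_log Vector of M mel log energies.
#' @param n_coef Number of cepstral coefficients L (`<= M`); default 13.
#' @return Numeric vector of `n_coef` coefficients.
#' @export
dct_cepstrum <- function(m_log, n_coef = 13L) {
  M <- length(m_log)
  if (n_coef > M)
    stop("n_coef (", n_coef, ") exceeds number of filters (", M, ")",
         call. = FALSE)
  as.numeric(dct_matrix(n_coef, M) %*% m_log)
}

# L x M matrix of cos(pi * l * (m - 0.5) / M), l = 1..L.
dct_matrix <- function(n_coef, M) {
  l <- seq_len(n_coef)
  m <- seq_len(M)
  outer(l, m, function(l, m) cos(pi * l * (m - 0.5) / M))
}

#' Per-minute MFCC matrix for a night
#'
#' Runs the full cepstral chain over a recording and aggregates frame-level
#' coefficient vectors into one vector per minute. A frame belongs to the
#' minute its start sample falls in; minutes are 1-based, `T =
#' ceil(duration / 60)`. Default aggregation is the per-coefficient mean
#' over the minute's frames; `"median"` and `"mean_sd"` (mean and standard
#' deviation concatenated) are available. A minute with no frames is filled
#' with zeros and flagged in the `empty_minutes` attribute.
#'
#' @param rec An [audio_recording].
#' @param cfg A [run_config].
#' @return A `T x L` matrix (rows `min<t>`, columns `c<l>`), with attributes
#'   `empty_minutes` and `standardized = FALSE`.
#' @export
minute_mfcc <- function(rec, cfg = run_config()) {
  stopifnot(inherits(rec, "audio_recording"))
  frame_length <- max(1L, round(cfg$frame_length_s * rec$sample_rate))
  hop_length <- max(1L, round(cfg$hop_length_s * rec$sample_rate))
  n_fft <- if (is.null(cfg$n_fft)) next_pow2(frame_length) else cfg$n_fft
  fmax <- if (is.null(cfg$fmax_hz)) rec$sample_rate / 2 else cfg$fmax_hz
  frames <- frame_and_window(rec, frame_length, hop_length, cfg$window_name)
  starts <- attr(frames, "frame_starts")
  bank <- build_mel_filterbank(cfg$n_mel_filters, rec$sample_rate, n_fft,
                               cfg$fmin_hz, fmax)
  ps <- power_spectra(frames, n_fft)
  M_log <- log(bank %*% ps + cfg$log_floor)
  cep <- dct_matrix(cfg$n_mfcc, cfg$n_mel_filters) %*% M_log   # L x n_frames
  minute_of <- starts %/% (60L * rec$sample_rate) + 1L
  n_min <- as.integer(ceiling(rec$duration_s / 60))
  agg <- aggregate_minutes(t(cep), minute_of, n_min, cfg$minute_aggregation)
  rownames(agg) <- paste0("min", seq_len(n_min))
  colnames(agg) <- if (cfg$minute_aggregation == "mean_sd")
    c(paste0("c", seq_len(cfg$n_mfcc)), paste0("c", seq_len(cfg$n_mfcc), "_sd"))
  else paste0("c", seq_len(cfg$n_mfcc))
  attr(agg, "standardized") <- FALSE
  agg
}

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

aggregate_minutes <- function(frame_feats, minute_of, n_min, method) {
  L <- ncol(frame_feats)
  out_cols <- if (method == "mean_sd") 2L * L else L
  out <- matrix(0, n_min, out_cols)
  present <- sort(unique(minute_of))
  for (t in present) {
    rows <- frame_feats[minute_of == t, , drop = FALSE]
    out[t, ] <- switch(method,
      mean = colMeans(rows),
      median = apply(rows, 2L, stats::median),
      mean_sd = c(colMeans(rows), apply(rows, 2L, stats::sd)),
      stop("unknown minute_aggregation: ", method, call. = FALSE))
  }
  empty <- setdiff(seq_len(n_min), present)
  out[is.na(out)] <- 0   # sd of a single frame
  attr(out, "empty_minutes") <- empty
  out
}

#' Standardize feature columns
#'
#' Fits a per-column scaler (mean and population standard deviation) on the
#' training matrix only and applies it to the training matrix and any
#' further matrices — test nights are transformed with the training scaler
#' so no information leaks across the split. Constant columns get a unit
#' divisor.
#'
#' @param train Numeric training matrix (`>= 2` rows).
#' @param ... Further matrices to transform with the fitted scaler.
#' @return List with `train`, `scaled` (list of transformed extras),
#'   and `scaler` (`center`, `scale`). The scaler is invertible via
#'   [unstandardize_features].
#' @export
standardize_features <- function(train, ...) {
  if (!is.matrix(train) || nrow(train) < 2L)
    stop("training matrix must have at least 2 rows", call. = FALSE)
  center <- colMeans(train)
  spread <- sqrt(colMeans(sweep(train, 2L, center)^2))
  spread[spread == 0] <- 1
  apply_one <- function(m) {
    out <- sweep(sweep(m, 2L, center), 2L, spread, `/`)
    attr(out, "standardized") <- TRUE
    out
  }
  extras <- lapply(list(...), apply_one)
  list(train = apply_one(train), scaled = extras,
       scaler = list(center = center, scale = spread))
}

#' @rdname standardize_features
#' @param m A standardized matrix.
#' @param scaler The `scaler` element returned by [standardize_features].
#' @export
unstandardize_features <- function(m, scaler) {
  sweep(sweep(m, 2L, scaler$scale, `*`), 2L, scaler$center, `+`)
}
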