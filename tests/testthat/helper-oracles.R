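# Independent brute-force oracles used across tests. Each reimplements the
# quantity under test from its definition, without touching the package's
# fast path.

# O(N^2) DFT: one-sided |X(k)|^2 by direct summation.
naive_dft_power <- function(x, n_fft) {
  x <- c(x, numeric(n_fft - length(x)))
  n <- seq_len(n_fft) - 1
  vapply(0:(n_fft / 2), function(k) {
    Mod(sum(x * exp(-2i * pi * n * k / n_fft)))^2
  }, numeric(1))
}

# Double-loop cepstral sum: C_l = sum_m M_m cos(pi l (m - 0.5) / M).
brute_dct <- function(m_log, n_coef) {
  M <- length(m_log)
  out <- numeric(n_coef)
  for (l in seq_len(n_coef)) {
    acc <- 0
    for (m in seq_len(M)) acc <- acc + m_log[m] * cos(pi * l * (m - 0.5) / M)
    out[l] <- acc
  }
  out
}

# Per-second discretization oracle for minute labeling. Events must have
# integer second bounds; marks seconds [start, end) then applies either rule.
persec_label_oracle <- function(events, night_s, rule, min_dur = 30) {
  n_min <- ceiling(night_s / 60)
  out <- integer(n_min)
  for (t in seq_len(n_min)) {
    sec_lo <- 60 * (t - 1); sec_hi <- min(60 * t, night_s)
    secs <- seq(sec_lo, sec_hi - 1)
    if (rule == "event_duration") {
      for (i in seq_len(nrow(events))) {
        dur <- events$end_s[i] - events$start_s[i]
        covered <- secs >= events$start_s[i] & secs < events$end_s[i]
        if (dur >= min_dur && any(covered)) out[t] <- 1L
      }
    } else {
      total <- 0
      for (s in secs)
        for (i in seq_len(nrow(events)))
          if (s >= events$start_s[i] && s < events$end_s[i])
            total <- total + 1
      if (total >= min_dur) out[t] <- 1L
    }
  }
  out
}

# All-pairs rank AUC: P(score_pos > score_neg), ties counted half.
pairs_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Evaluate expr under a fixed seed without disturbing the ambient stream.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Random integer-second apnea event set that fits a night, non-overlapping.
random_event_set <- function(night_s, max_events = 6) {
  n <- sample(0:max_events, 1)
  if (n == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      kind = character(0)))
  bounds <- sort(sample(0:night_s, 2 * n))
  starts <- bounds[seq(1, 2 * n, by = 2)]
  ends <- bounds[seq(2, 2 * n, by = 2)]
  keep <- ends > starts
  data.frame(start_s = starts[keep], end_s = ends[keep],
             kind = rep("apnea", sum(keep)))
}

# Tiny tone-burst recording for audio-path tests.
tone_recording <- function(dur_s = 2, fs = 4000, freq = 250) {
  audio_recording(0.5 * sin(2 * pi * freq * (0:(dur_s * fs - 1)) / fs), fs)
}

# A linearly separable two-class fixture (built by construction).
separable_fixture <- function(n = 200, p = 4, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + ifelse(y == 1, 4, -4)
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}
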