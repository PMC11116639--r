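test_that("frame count matches the sliding-window formula and a brute loop", {
  rec <- audio_recording(rnorm(8000), 8000)
  f <- frame_and_window(rec, 200, 80, "rect")
  # brute-force slide
  n <- 0; s <- 1
  while (s + 200 - 1 <= 8000) { n <- n + 1; s <- s + 80 }
  expect_equal(ncol(f), n)
  expect_equal(ncol(f), (8000 - 200) %/% 80 + 1)   # 98

  one <- frame_and_window(audio_recording(rnorm(400), 8000), 400, 160)
  expect_equal(ncol(one), 1L)
  expect_error(frame_and_window(audio_recording(rnorm(100), 8000), 400, 160),
               "too short")
})

test_that("windowing multiplies frames elementwise; rect keeps them verbatim", {
  const <- audio_recording(rep(0.5, 1000), 1000)
  f <- frame_and_window(const, 100, 50, "rect")
  expect_true(all(f == 0.5))
  expect_equal(ncol(unique(t(f))), 100L)  # all frames identical

  fh <- frame_and_window(const, 100, 50, "hamming")
  expect_equal(fh[, 1], 0.5 * analysis_window("hamming", 100))
})

test_that("power spectrum matches the closed form for a bin-aligned cosine", {
  n_fft <- 256
  x <- cos(2 * pi * 16 * (0:(n_fft - 1)) / n_fft)
  ps <- power_spectrum(x, n_fft)
  expect_equal(ps[16 + 1], (n_fft / 2)^2, tolerance = 1e-9)
  expect_lt(max(ps[-(16 + 1)]), 1e-12)
  expect_true(all(power_spectrum(numeric(128), 128) == 0))
  expect_error(power_spectrum(rnorm(100), 100), "power of two")
})

test_that("FFT power path equals the naive DFT oracle on random frames", {
  set.seed(41)
  for (rep in 1:100) {
    len <- sample(c(64, 100, 128, 256), 1)
    n_fft <- 256
    x <- rnorm(len)
    fast <- power_spectrum(x, n_fft)
    slow <- naive_dft_power(x, n_fft)
    expect_lt(max(abs(fast - slow)) / max(slow), 1e-9)
  }
})

test_that("one-sided spectral energy obeys Parseval (rect window)", {
  set.seed(7)
  x <- rnorm(256)
  ps <- power_spectrum(x, 256)
  # double interior bins to recover the two-sided sum
  two_sided <- ps[1] + ps[129] + 2 * sum(ps[2:128])
  expect_equal(two_sided / 256, sum(x^2), tolerance = 1e-6)
})

test_that("mel mapping is the standard closed form and a bijection", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2), tolerance = 1e-12)
  set.seed(2)
  f <- runif(1000, 0, 4000)
  expect_lt(max(abs(mel_to_hz(hz_to_mel(f)) - f)), 1e-9)
  expect_true(all(diff(hz_to_mel(sort(f))) > 0))
  expect_error(hz_to_mel(-1), "nonnegative")
})

test_that("mel filterbank is triangular with equally spaced apexes and full coverage", {
  bank <- build_mel_filterbank(26, 8000, 512, 0, 4000)
  expect_equal(dim(bank), c(26L, 257L))
  expect_true(all(bank >= 0 & bank <= 1))
  centers <- attr(bank, "center_freqs_hz")
  expect_true(all(diff(centers) > 0))
  # apex mel positions equally spaced (recomputed independently)
  mel_centers <- 2595 * log10(1 + centers / 700)
  expect_lt(diff(range(diff(mel_centers))), 1e-9)
  # unimodality: each row rises then falls
  for (m in seq_len(26)) {
    r <- bank[m, ]
    peak <- which.max(r)
    expect_true(all(diff(r[seq_len(peak)]) >= -1e-12))
    expect_true(all(diff(r[peak:length(r)]) <= 1e-12))
  }
  # every bin between first and last apex is covered by some filter
  bin_hz <- (0:256) * 8000 / 512
  inner <- bin_hz > centers[1] & bin_hz < centers[26]
  expect_true(all(colSums(bank)[inner] > 0))
  expect_error(build_mel_filterbank(26, 8000, 512, 4000, 100), "fmin")
})

test_that("mel log energies follow the filter sums with a floored log", {
  bank <- build_mel_filterbank(10, 8000, 256)
  zero <- mel_log_energies(numeric(129), bank, log_floor = 1e-10)
  expect_true(all(zero$S == 0))
  expect_true(all(zero$M_log == log(1e-10)))

  flat <- mel_log_energies(rep(1, 129), bank)
  expect_equal(flat$S, rowSums(bank), tolerance = 1e-12)

  set.seed(3)
  ps <- runif(129, 0.5, 2)
  a <- mel_log_energies(ps, bank)$M_log
  b <- mel_log_energies(2 * ps, bank)$M_log
  expect_equal(b - a, rep(log(2), 10), tolerance = 1e-8)
  expect_error(mel_log_energies(numeric(100), bank), "does not match")
})

test_that("cepstral transform equals its printed sum and brute-force oracle", {
  # constant log energies: the cosine sum vanishes for every l >= 1
  expect_lt(max(abs(dct_cepstrum(rep(3.7, 26), 13))), 1e-10)
  # single unit energy at m = 1, M = 4, l = 1
  expect_equal(dct_cepstrum(c(1, 0, 0, 0), 1), cos(pi * 0.5 / 4),
               tolerance = 1e-12)
  set.seed(11)
  for (rep in 1:100) {
    M <- sample(4:30, 1)
    L <- sample(seq_len(M), 1)
    m_log <- rnorm(M)
    expect_lt(max(abs(dct_cepstrum(m_log, L) - brute_dct(m_log, L))), 1e-10)
  }
  expect_error(dct_cepstrum(rnorm(5), 6), "exceeds")
})

test_that("minute aggregation averages the per-frame cepstra it covers", {
  rec <- tone_recording(125, 2000, 300)   # 2 min 5 s
  cfg <- run_config()
  m <- minute_mfcc(rec, cfg)
  expect_equal(dim(m), c(3L, 13L))
  # both full minutes hold identical audio -> identical rows
  expect_equal(m[1, ], m[2, ], tolerance = 1e-9)

  # brute-force recomputation of minute 1 by an explicit per-frame loop
  fs <- rec$sample_rate
  flen <- round(cfg$frame_length_s * fs); hop <- round(cfg$hop_length_s * fs)
  n_fft <- 64
  bank <- build_mel_filterbank(cfg$n_mel_filters, fs, n_fft)
  starts <- seq(0, rec$n_samples - flen, by = hop)
  in_min1 <- starts < 60 * fs
  acc <- matrix(0, 0, 13)
  w <- analysis_window("hamming", flen)
  for (s in starts[in_min1]) {
    fr <- rec$samples[(s + 1):(s + flen)] * w
    me <- mel_log_energies(power_spectrum(fr, n_fft), bank, cfg$log_floor)
    acc <- rbind(acc, dct_cepstrum(me$M_log, 13))
  }
  expect_equal(unname(m[1, ]), colMeans(acc), tolerance = 1e-8)
})

test_that("identical recording and config give bit-identical features", {
  rec <- tone_recording(61, 2000, 140)
  expect_identical(minute_mfcc(rec), minute_mfcc(rec))
})

test_that("standardization fits on training rows only and inverts exactly", {
  z <- standardize_features(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(unname(z$train[, 1]),
               c(-1.2247448713915890, 0, 1.2247448713915890),
               tolerance = 1e-12)
  expect_true(all(z$train[, 2] == 0))   # constant column: no blow-up

  set.seed(4)
  train <- matrix(rnorm(60), 20, 3)
  test <- matrix(rnorm(30, mean = 5), 10, 3)
  out <- standardize_features(train, test)
  expect_lt(max(abs(colMeans(out$train))), 1e-12)
  expect_equal(unname(apply(out$train, 2, function(v) mean(v^2))),
               rep(1, 3), tolerance = 1e-8)
  # test columns keep their shift: no leakage of test statistics
  expect_gt(min(colMeans(out$scaled[[1]])), 1)
  back <- unstandardize_features(out$scaled[[1]], out$scaler)
  expect_lt(max(abs(back - test)), 1e-10)
  expect_error(standardize_features(matrix(1, 1, 2)), "at least 2 rows")
})
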