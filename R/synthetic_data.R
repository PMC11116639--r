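#' Specification for one synthetic night
#'
#' Defines the study conditions a simulated overnight recording emulates:
#' an 8 h night sampled at 8 kHz by default, breath-synchronous snore
#' bursts (a harmonic stack at a per-night fundamental, amplitude-modulated
#' by a per-breath envelope) over a white-noise floor, with apnea modeled
#' as intervals where snoring is silenced while the noise floor remains.
#' Event durations default to uniform 20–90 s so that both sub-30 s
#' (unlabeled) and >= 30 s (labeled) events occur, exercising the
#' 30-second labeling rule.
#'
#' @param duration_min Night length in minutes (default 480 = 8 h).
#' @param sample_rate Sampling rate in Hz (default 8000).
#' @param target_ahi Requested events per hour (`>= 0`).
#' @param apnea_duration_s Length-2 range of event durations, seconds.
#' @param breath_period_s Breathing cycle length, seconds (default 4).
#' @param snore_fundamental_hz Range the per-night snore fundamental is
#'   drawn from, Hz (default 80–150).
#' @param snore_gain Peak snore amplitude (default 0.25).
#' @param background_noise_sd White noise standard deviation (default 0.01).
#' @param min_gap_s Minimum silence-free gap between events, seconds.
#' @param seed Integer seed making the night fully reproducible.
#' @return A list of class `synthetic_night_spec`.
#' @export
synthetic_night_spec <- function(duration_min = 480, sample_rate = 8000L,
                                 target_ahi = 10,
                                 apnea_duration_s = c(20, 90),
                                 breath_period_s = 4,
                                 snore_fundamental_hz = c(80, 150),
                                 snore_gain = 0.25,
                                 background_noise_sd = 0.01,
                                 min_gap_s = 5, seed = 1L) {
  if (target_ahi < 0) stop("target_ahi must be nonnegative", call. = FALSE)
  structure(list(duration_min = duration_min,
                 sample_rate = as.integer(sample_rate),
                 target_ahi = target_ahi,
                 apnea_duration_s = apnea_duration_s,
                 breath_period_s = breath_period_s,
                 snore_fundamental_hz = snore_fundamental_hz,
                 snore_gain = snore_gain,
                 background_noise_sd = background_noise_sd,
                 min_gap_s = min_gap_s, seed = as.integer(seed)),
            class = "synthetic_night_spec")
}

#' Reduced profile for fast full-path runs
#'
#' A 20-minute night at 4 kHz with 15–40 s events, so the entire audio
#' pipeline runs in seconds; the shorter durations keep high-AHI nights
#' packable into a 20-minute window.
#'
#' @param ... Overrides passed to [synthetic_night_spec].
#' @export
short_night_spec <- function(...) {
  args <- utils::modifyList(
    list(duration_min = 20, sample_rate = 4000L,
         apnea_duration_s = c(15, 40)),
    list(...))
  do.call(synthetic_night_spec, args)
}

#' Simulate one overnight recording with ground truth
#'
#' Generates audio, the exact apnea annotations, and the per-minute truth
#' record for one night. `round(target_ahi * hours)` events with durations
#' uniform in the configured range are placed uniformly at random without
#' overlap (respecting the minimum gap); snoring is silenced inside each
#' event. The same `(spec, seed)` always yields bit-identical audio and
#' annotations.
#'
#' @param spec A [synthetic_night_spec].
#' @param seed Optional seed override (defaults to `spec$seed`).
#' @param label_rule,min_duration_s Passed to [label_minutes] for the truth
#'   record.
#' @return A list of class `synthetic_night`: `audio` ([audio_recording]),
#'   `events` ([event_list]), `truth_record` (per-minute 0/1),
#'   `realized_ahi` (placed events per hour), `spec`, `seed`.
#' @export
simulate_night <- function(spec, seed = spec$seed,
                           label_rule = "event_duration",
                           min_duration_s = 30) {
  stopifnot(inherits(spec, "synthetic_night_spec"))
  dur_s <- spec$duration_min * 60
  hours <- dur_s / 3600
  n_events <- round(spec$target_ahi * hours)
  out <- with_local_rng(seed, {
    f0 <- stats::runif(1, spec$snore_fundamental_hz[1],
                       spec$snore_fundamental_hz[2])
    ev <- place_events(n_events, dur_s, spec$apnea_duration_s,
                       spec$min_gap_s)
    audio <- synth_audio(dur_s, spec$sample_rate, f0, spec$breath_period_s,
                         spec$snore_gain, spec$background_noise_sd, ev)
    list(f0 = f0, ev = ev, audio = audio)
  })
  events <- event_list(
    data.frame(start_s = out$ev$start, end_s = out$ev$end,
               kind = if (n_events) "apnea" else character(0)),
    night_duration_s = dur_s)
  truth <- label_minutes(events, label_rule, min_duration_s)
  structure(list(audio = audio_recording(out$audio, spec$sample_rate),
                 events = events, truth_record = truth,
                 realized_ahi = n_events / hours,
                 snore_fundamental_hz = out$f0,
                 spec = spec, seed = as.integer(seed)),
            class = "synthetic_night")
}

#' @export
print.synthetic_night <- function(x, ...) {
  cat(sprintf(
    "<synthetic_night> %.0f min @ %d Hz, %d events, realized AHI %.2f\n",
    x$spec$duration_min, x$spec$sample_rate, nrow(x$events$events),
    x$realized_ahi))
  invisible(x)
}

# Uniform non-overlapping placement: draw durations, then scatter the
# leftover slack uniformly. Errors if the night cannot hold the requested
# events with the required gaps.
place_events <- function(n, night_s, dur_range, gap_s) {
  if (n == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  durs <- stats::runif(n, dur_range[1], dur_range[2])
  slack <- night_s - sum(durs) - gap_s * (n + 1)
  if (slack < 0)
    stop("cannot place ", n, " events totalling ", round(sum(durs)),
         " s (plus gaps) in a ", night_s, " s night", call. = FALSE)
  u <- sort(stats::runif(n, 0, slack))
  starts <- u + c(0, cumsum(durs))[seq_len(n)] + gap_s * seq_len(n)
  data.frame(start = starts, end = starts + durs)
}

# Breath-synchronous snore bursts + noise, silenced inside events.
synth_audio <- function(dur_s, fs, f0, breath_period, gain, noise_sd, ev,
                        duty = 0.4, n_harm = 5L) {
  n <- as.integer(round(dur_s * fs))
  tt <- (seq_len(n) - 1L) / fs
  phase <- (tt %% breath_period) / breath_period
  env <- numeric(n)
  on <- phase < duty
  env[on] <- sin(pi * phase[on] / duty)^2
  stack <- numeric(n)
  for (h in seq_len(n_harm))
    stack <- stack + 0.7^(h - 1) * sin(2 * pi * h * f0 * tt)
  stack <- stack / sum(0.7^(seq_len(n_harm) - 1))
  snore <- gain * env * stack
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$start[i] * fs) + 1L
    i1 <- min(n, ceiling(ev$end[i] * fs))
    snore[i0:i1] <- 0
  }
  snore + stats::rnorm(n, 0, noise_sd)
}

#' Simulate a cohort of nights with a severity mix
#'
#' Draws per-night severity classes in the given proportions (largest
#' remainder rounding, so an exactly balanced mix yields an exactly
#' balanced cohort), then a per-night target AHI uniform within the class
#' band — normal (0, 5), mild (5, 15), moderate (15, 30), severe (30, 45);
#' the severe band is capped where a night can still physically hold the
#' events. The realized event count is snapped inside the class band so
#' every night's realized AHI grades back to its intended class. Per-night
#' seeds derive deterministically from the master seed.
#'
#' @param n_nights Number of nights (`>= 1`).
#' @param severity_mix Proportions over the four classes, summing to 1.
#' @param seed Master seed.
#' @param template A [synthetic_night_spec] supplying everything except
#'   `target_ahi` and `seed`.
#' @return List of [simulate_night] results; attribute `manifest` is a
#'   data.frame (night, class, target_ahi, realized_ahi, seed).
#' @export
simulate_cohort <- function(n_nights, severity_mix = rep(0.25, 4), seed = 1L,
                            template = synthetic_night_spec()) {
  if (n_nights < 1) stop("n_nights must be at least 1", call. = FALSE)
  if (length(severity_mix) != 4L || any(severity_mix < 0) ||
      abs(sum(severity_mix) - 1) > 1e-8)
    stop("severity_mix must be four nonnegative proportions summing to 1",
         call. = FALSE)
  counts <- largest_remainder(severity_mix * n_nights)
  classes <- rep(0:3, times = counts)
  bands <- rbind(c(0, 5), c(5, 15), c(15, 30), c(30, 45))
  hours <- template$duration_min / 60
  nights <- vector("list", n_nights)
  man <- vector("list", n_nights)
  for (i in seq_len(n_nights)) {
    cl <- classes[i]
    lo <- bands[cl + 1L, 1L]; hi <- bands[cl + 1L, 2L]
    night_seed <- (seed * 1000L + i) %% .Machine$integer.max
    target <- with_local_rng(night_seed, stats::runif(1, lo, hi))
    # snap the event count so realized AHI stays inside the class band
    n_ev <- round(target * hours)
    n_lo <- ceiling(lo * hours); n_hi <- ceiling(hi * hours) - 1L
    n_ev <- min(max(n_ev, n_lo), n_hi)
    sp <- template
    sp$target_ahi <- n_ev / hours
    sp$seed <- night_seed
    nights[[i]] <- simulate_night(sp)
    nights[[i]]$class <- cl
    man[[i]] <- data.frame(night = i, class = cl,
                           target_ahi = target,
                           realized_ahi = nights[[i]]$realized_ahi,
                           seed = night_seed)
  }
  attr(nights, "manifest") <- do.call(rbind, man)
  nights
}

largest_remainder <- function(x) {
  base <- floor(x)
  rem <- x - base
  short <- round(sum(x)) - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}
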