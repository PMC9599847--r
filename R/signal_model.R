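#' Signal model configuration
#'
#' Parameters of the synthetic chest-wall vibration model. A measurement is a
#' train of S1/S2 heart-sound wavelets amplitude-modulated by respiration,
#' riding on a low-frequency respiration wave, plus optional congestion,
#' murmur and wheeze components and white measurement noise.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Recording length, s.
#' @param heart_rate_mean,heart_rate_sd Heart rate mean and beat-to-beat
#'   variability, bpm.
#' @param systole_fraction Fraction of the RR interval from S1 to S2.
#' @param s1_center_freq,s2_center_freq Center frequencies of the S1/S2
#'   wavelets, Hz.
#' @param s1_amp,s2_amp Wavelet peak amplitudes, arbitrary units.
#' @param resp_rate Respiratory rate, breaths/min.
#' @param inhale_fraction Fraction of the respiratory cycle spent inhaling.
#' @param resp_mod_depth Depth of respiratory amplitude modulation of the
#'   heart sounds (0 = none).
#' @param baseline_gain Amplitude of the respiration wave itself in the
#'   composite signal.
#' @param congestion_effect Dimensionless effect size `d >= 0`; 0 means cases
#'   and controls are distributed identically.
#' @param congestion_band Frequency band (Hz) carrying the congestion
#'   signature during inhalation.
#' @param murmur_amp Amplitude of the systolic murmur added for subjects with
#'   a valvular disorder (label-independent nuisance).
#' @param wheeze_amp Amplitude of the expiratory wheeze tone added for
#'   subjects with a respiratory condition (label-independent nuisance).
#' @param noise_sd White measurement-noise standard deviation.
#' @param seed Base seed for per-measurement RNG streams.
#' @return A list of class `signal_model_config`.
#' @export
signal_model_config <- function(fs = 500, duration = 120,
                                heart_rate_mean = 70, heart_rate_sd = 5,
                                systole_fraction = 0.35,
                                s1_center_freq = 25, s2_center_freq = 45,
                                s1_amp = 1, s2_amp = 0.6,
                                resp_rate = 15, inhale_fraction = 0.4,
                                resp_mod_depth = 0.25, baseline_gain = 0.5,
                                congestion_effect = 0, congestion_band = c(2, 4),
                                murmur_amp = 0.15, wheeze_amp = 0.15,
                                noise_sd = 0.05, seed = 1) {
  cfg <- as.list(environment())
  check_scalar(fs, "fs", 0, open_lo = TRUE)
  check_scalar(duration, "duration", 0, open_lo = TRUE)
  check_scalar(heart_rate_mean, "heart_rate_mean", 0, open_lo = TRUE)
  check_scalar(heart_rate_sd, "heart_rate_sd", 0)
  check_scalar(systole_fraction, "systole_fraction", 0, 0.5, TRUE, TRUE)
  check_scalar(inhale_fraction, "inhale_fraction", 0, 1, TRUE, TRUE)
  check_scalar(resp_rate, "resp_rate", 0, open_lo = TRUE)
  check_scalar(congestion_effect, "congestion_effect", 0)
  check_scalar(noise_sd, "noise_sd", 0)
  if (length(congestion_band) != 2L || congestion_band[1] <= 0 ||
      congestion_band[2] <= congestion_band[1] || congestion_band[2] >= fs / 2)
    stopf("'congestion_band' must be (low, high) with 0 < low < high < fs/2")
  if (fs <= 4 * max(s1_center_freq, s2_center_freq))
    stopf("fs must exceed 4 x max(s1_center_freq, s2_center_freq)")
  structure(cfg, class = "signal_model_config")
}

#' Landmark set constructor
#'
#' Bundles S1/S2 event times and inhale/exhale intervals for one buffer or
#' measurement. Times are seconds from the start of the containing signal.
#'
#' @param s1_times,s2_times Strictly increasing event times, s.
#' @param inhale_intervals,exhale_intervals Two-column matrices (or lists of
#'   pairs) of `[start, end)` interval bounds, s.
#' @param quality_ok Logical; `FALSE` marks a low-quality buffer whose
#'   landmarks are unusable.
#' @return A list of class `landmark_set`.
#' @export
landmark_set <- function(s1_times = numeric(0), s2_times = numeric(0),
                         inhale_intervals = NULL, exhale_intervals = NULL,
                         quality_ok = TRUE) {
  s1_times <- as.numeric(s1_times); s2_times <- as.numeric(s2_times)
  if (is.unsorted(s1_times, strictly = TRUE)) stopf("s1_times must be strictly increasing")
  if (is.unsorted(s2_times, strictly = TRUE)) stopf("s2_times must be strictly increasing")
  structure(list(s1_times = s1_times, s2_times = s2_times,
                 inhale_intervals = as_interval_matrix(inhale_intervals),
                 exhale_intervals = as_interval_matrix(exhale_intervals),
                 quality_ok = isTRUE(quality_ok)),
            class = "landmark_set")
}

# Gabor-like damped-sinusoid wavelet; default ~70 ms support, matching the
# duration of valve-closure transients and keeping the spectral peak at the
# nominal center frequency despite the short duration
heart_wavelet <- function(fs, center_freq, sigma = 0.01) {
  half <- ceiling(3.5 * sigma * fs)
  t <- (-half:half) / fs
  exp(-t^2 / (2 * sigma^2)) * sin(2 * pi * center_freq * t)
}

# add wavelet w centered at sample index center into x (in place semantics)
add_at <- function(x, w, center) {
  half <- (length(w) - 1L) %/% 2L
  i0 <- center - half; i1 <- center + half
  j0 <- max(1L, i0); j1 <- min(length(x), i1)
  if (j0 > j1) return(x)
  x[j0:j1] <- x[j0:j1] + w[(j0 - i0 + 1L):(j1 - i0 + 1L)]
  x
}

#' Synthesize an S1/S2 heartbeat wavelet train
#'
#' Places Gabor-like wavelets at S1 onsets spaced by RR intervals
#' `60/heart_rate_mean` with Gaussian beat-to-beat jitter, and at S2 onsets a
#' fixed `systole_fraction` of each RR later. Draws from the current R RNG
#' stream; callers seed it.
#'
#' @param cfg A [signal_model_config()].
#' @return A list with `signal` (numeric vector), `s1_times`, `s2_times`.
#' @export
synthesize_heartbeat_train <- function(cfg) {
  stopifnot(inherits(cfg, "signal_model_config"))
  fs <- cfg$fs; n <- round(fs * cfg$duration)
  rr_mean <- 60 / cfg$heart_rate_mean
  # bpm jitter translated to RR-interval jitter at the mean rate
  rr_sd <- 60 * cfg$heart_rate_sd / cfg$heart_rate_mean^2
  t_max <- cfg$duration
  s1 <- numeric(0); s2 <- numeric(0)
  t <- rr_mean / 2
  while (t < t_max) {
    rr <- rr_mean + if (rr_sd > 0) stats::rnorm(1, 0, rr_sd) else 0
    rr <- max(rr, 0.25) # physiological floor (240 bpm)
    s1 <- c(s1, t)
    s2t <- t + cfg$systole_fraction * rr
    if (s2t < t_max) s2 <- c(s2, s2t)
    t <- t + rr
  }
  x <- numeric(n)
  w1 <- cfg$s1_amp * heart_wavelet(fs, cfg$s1_center_freq)
  w2 <- cfg$s2_amp * heart_wavelet(fs, cfg$s2_center_freq)
  for (ti in s1) x <- add_at(x, w1, round(ti * fs) + 1L)
  for (ti in s2) x <- add_at(x, w2, round(ti * fs) + 1L)
  list(signal = x, s1_times = s1, s2_times = s2)
}

#' Synthesize an asymmetric respiration wave
#'
#' Piecewise-sinusoidal cycle of period `60/resp_rate`: a rising (inhale)
#' segment occupying `inhale_fraction` of the cycle from -1 to +1, and a
#' falling (exhale) segment back to -1. Deterministic given the config.
#'
#' @param cfg A [signal_model_config()].
#' @return A list with `wave` (in `[-1, 1]`), `inhale_intervals` and
#'   `exhale_intervals` (two-column matrices, s).
#' @export
synthesize_respiration_wave <- function(cfg) {
  stopifnot(inherits(cfg, "signal_model_config"))
  fs <- cfg$fs; n <- round(fs * cfg$duration)
  period <- 60 / cfg$resp_rate
  t_in <- cfg$inhale_fraction * period
  t <- (seq_len(n) - 1) / fs
  tau <- t %% period
  wave <- ifelse(tau < t_in,
                 -cos(pi * tau / t_in),
                 cos(pi * (tau - t_in) / (period - t_in)))
  starts <- seq(0, cfg$duration - 1e-9, by = period)
  inh <- cbind(starts, pmin(starts + t_in, cfg$duration))
  exh <- cbind(starts + t_in, pmin(starts + period, cfg$duration))
  exh <- exh[exh[, 1] < cfg$duration, , drop = FALSE]
  list(wave = wave,
       inhale_intervals = unname(inh[inh[, 2] > inh[, 1], , drop = FALSE]),
       exhale_intervals = unname(exh[exh[, 2] > exh[, 1], , drop = FALSE]))
}

# unit-RMS band-limited Gaussian noise
band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  x <- butterworth_filter(x, fs, band, "bandpass", order = 2)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Synthesize one vibration measurement for a subject
#'
#' Composes the heartbeat train (respiration-modulated), the respiration
#' baseline, a congestion term for congested subjects (inhale-gated
#' band-limited noise in `congestion_band` plus sparse crackle transients,
#' amplitude proportional to `congestion_effect * noise_sd`), a systolic
#' murmur for valvular disorder, an expiratory wheeze tone for respiratory
#' conditions, and white noise. The RNG stream is derived from
#' `(cfg$seed, subject_id, measurement_id)` so any measurement regenerates
#' identically in isolation.
#'
#' @param subject One-row `data.frame` (a [generate_cohort()] row) or list
#'   with at least `subject_id`, `congested`, `respiratory_condition`,
#'   `valvular_disorder`.
#' @param cfg A [signal_model_config()].
#' @param measurement_id Identifier; defaults to `<subject_id>_M01`.
#' @return A list of class `vibration_measurement`: `subject_id`,
#'   `measurement_id`, `fs`, `samples`, `truth_landmarks` (a [landmark_set()]).
#' @export
synthesize_measurement <- function(subject, cfg,
                                   measurement_id = paste0(subject$subject_id, "_M01")) {
  stopifnot(inherits(cfg, "signal_model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(measurement_seed(cfg$seed, subject$subject_id, measurement_id))

  fs <- cfg$fs; n <- round(fs * cfg$duration)
  heart <- synthesize_heartbeat_train(cfg)
  resp <- synthesize_respiration_wave(cfg)
  t <- (seq_len(n) - 1) / fs
  x <- heart$signal * (1 + cfg$resp_mod_depth * resp$wave) +
    cfg$baseline_gain * resp$wave

  inhale_gate <- as.numeric(in_intervals(t, resp$inhale_intervals))
  if (isTRUE(subject$congested) && cfg$congestion_effect > 0 && cfg$noise_sd > 0) {
    amp <- cfg$congestion_effect * cfg$noise_sd
    x <- x + amp * band_noise(n, fs, cfg$congestion_band) * inhale_gate
    # sparse crackle-like transients, ~15 ms, confined to inhalation
    crackle <- cfg$congestion_effect * cfg$noise_sd * heart_wavelet(fs, 40, sigma = 0.004)
    for (iv in seq_len(nrow(resp$inhale_intervals))) {
      k <- stats::rpois(1, cfg$congestion_effect)
      if (k > 0) {
        at <- stats::runif(k, resp$inhale_intervals[iv, 1], resp$inhale_intervals[iv, 2])
        for (ti in at) x <- add_at(x, crackle, round(ti * fs) + 1L)
      }
    }
  }
  if (isTRUE(subject$valvular_disorder) && cfg$murmur_amp > 0) {
    sys_iv <- cbind(heart$s1_times[seq_along(heart$s2_times)], heart$s2_times)
    gate <- as.numeric(in_intervals(t, sys_iv))
    x <- x + cfg$murmur_amp * band_noise(n, fs, c(20, 60)) * gate
  }
  if (isTRUE(subject$respiratory_condition) && cfg$wheeze_amp > 0) {
    gate <- as.numeric(in_intervals(t, resp$exhale_intervals))
    x <- x + cfg$wheeze_amp * sin(2 * pi * 30 * t) * gate
  }
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)

  structure(list(subject_id = subject$subject_id,
                 measurement_id = measurement_id,
                 fs = fs, samples = x,
                 truth_landmarks = landmark_set(
                   s1_times = heart$s1_times, s2_times = heart$s2_times,
                   inhale_intervals = resp$inhale_intervals,
                   exhale_intervals = resp$exhale_intervals)),
            class = "vibration_measurement")
}

#' Synthesize all measurements for a cohort
#'
#' @param cohort A [generate_cohort()] table.
#' @param cfg A [signal_model_config()].
#' @return A list of `vibration_measurement`, `n_measurements` per subject,
#'   ids `<subject_id>_M01`, `_M02`, ...
#' @export
simulate_measurements <- function(cohort, cfg) {
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    subject <- cohort[i, ]
    for (j in seq_len(subject$n_measurements)) {
      mid <- sprintf("%s_M%02d", subject$subject_id, j)
      out[[mid]] <- synthesize_measurement(subject, cfg, measurement_id = mid)
    }
  }
  out
}
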