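#' Band/phase sectioning grid for spectrogram features
#'
#' Defines the frequency bands and respiratory phases used to section the
#' spectrogram. Defaults are octave bands from 0.5 to 64 Hz (including the
#' physiologically interesting 2-4 Hz band) crossed with the inhale, exhale
#' and full-buffer phases.
#'
#' @param bands List of `c(low, high)` pairs, Hz; must be non-overlapping and
#'   increasing.
#' @param phases Subset of `c("inhale", "exhale", "full")`.
#' @return A list of class `band_phase_grid`.
#' @export
band_phase_grid <- function(bands = list(c(0.5, 1), c(1, 2), c(2, 4), c(4, 8),
                                         c(8, 16), c(16, 32), c(32, 64)),
                            phases = c("inhale", "exhale", "full")) {
  lows <- vapply(bands, `[`, numeric(1), 1)
  highs <- vapply(bands, `[`, numeric(1), 2)
  if (any(highs <= lows)) stopf("each band needs low < high")
  if (length(bands) > 1 && any(lows[-1] < highs[-length(highs)]))
    stopf("bands must be non-overlapping and increasing")
  phases <- match.arg(phases, c("inhale", "exhale", "full"), several.ok = TRUE)
  structure(list(bands = bands, phases = phases), class = "band_phase_grid")
}

band_label <- function(band) sprintf("band_%g_%g", band[1], band[2])

#' Time-domain landmark features of one buffer
#'
#' Distances and mean envelope amplitudes between the heart-sound and
#' respiratory landmarks: mean/SD of the S1-to-S2 (systolic), S2-to-next-S1
#' (diastolic) and S1-to-S1 (RR) intervals, envelope amplitude statistics at
#' S1 and S2, the S2/S1 amplitude ratio, the RR coefficient of variation,
#' heart and respiratory rates, and the inhale/exhale duration ratio.
#' Single-observation standard deviations are defined as 0 so vectors stay
#' complete.
#'
#' @param b A `signal_buffer`.
#' @param lm A [landmark_set()] for that buffer.
#' @param hp_cutoff,smooth_ms Envelope construction parameters (matching the
#'   detector's).
#' @return Named numeric vector with attribute `quality_ok`; all `NA` with
#'   `quality_ok = FALSE` when the landmarks are empty.
#' @export
time_domain_features <- function(b, lm, hp_cutoff = 15, smooth_ms = 20) {
  nms <- c("s1s2_mean", "s1s2_sd", "s2s1_mean", "s2s1_sd", "rr_mean", "rr_sd",
           "env_s1_mean", "env_s1_sd", "env_s2_mean", "env_s2_sd",
           "s2_s1_amp_ratio", "rr_cv", "heart_rate_bpm", "resp_rate_bpm",
           "inhale_exhale_ratio")
  empty <- structure(rep(NA_real_, length(nms)), names = nms, quality_ok = FALSE)
  if (!lm$quality_ok || length(lm$s1_times) < 2 || length(lm$s2_times) < 1)
    return(empty)
  duration <- length(b$samples) / b$fs
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

  s1 <- lm$s1_times; s2 <- lm$s2_times
  # pair each S1 with the first S2 before the next S1
  nxt <- c(s1[-1], Inf)
  s1s2 <- unlist(lapply(seq_along(s1), function(i) {
    cand <- s2[s2 > s1[i] & s2 < nxt[i]]
    if (length(cand)) cand[1] - s1[i] else numeric(0)
  }))
  s2s1 <- unlist(lapply(seq_along(s2), function(i) {
    cand <- s1[s1 > s2[i]]
    if (length(cand)) cand[1] - s2[i] else numeric(0)
  }))
  rr <- diff(s1)

  env <- signal_envelope(butterworth_filter(b$samples, b$fs, hp_cutoff, "highpass"),
                         b$fs, smooth_ms = smooth_ms)
  at <- function(tt) env[pmin(pmax(round(tt * b$fs) + 1L, 1L), length(env))]
  e1 <- at(s1); e2 <- at(s2)

  inh <- lm$inhale_intervals; exh <- lm$exhale_intervals
  inh_len <- if (nrow(inh)) mean(inh[, 2] - inh[, 1]) else NA_real_
  exh_len <- if (nrow(exh)) mean(exh[, 2] - exh[, 1]) else NA_real_

  vals <- c(
    s1s2_mean = mean(s1s2), s1s2_sd = sd0(s1s2),
    s2s1_mean = mean(s2s1), s2s1_sd = sd0(s2s1),
    rr_mean = mean(rr), rr_sd = sd0(rr),
    env_s1_mean = mean(e1), env_s1_sd = sd0(e1),
    env_s2_mean = mean(e2), env_s2_sd = sd0(e2),
    s2_s1_amp_ratio = mean(e2) / mean(e1),
    rr_cv = sd0(rr) / mean(rr),
    heart_rate_bpm = 60 / mean(rr),
    resp_rate_bpm = nrow(inh) / duration * 60,
    inhale_exhale_ratio = inh_len / exh_len
  )
  structure(vals[nms], names = nms, quality_ok = TRUE)
}

#' Landmark-sectioned spectrogram features of one buffer
#'
#' Sections the spectrogram vertically by frequency band and horizontally by
#' respiratory phase and saves the mean power of each cross-section, plus the
#' inhale/exhale energy ratio per band. A phase with no spectrogram frames
#' yields `NA` for its cells.
#'
#' @param sg An `lv_spectrogram`.
#' @param lm A [landmark_set()] (for the phase intervals).
#' @param grid A [band_phase_grid()]; all bands must lie under the Nyquist
#'   frequency of `sg`.
#' @return Named numeric vector (`|bands| * |phases| + |bands|` values).
#' @export
frequency_domain_features <- function(sg, lm, grid = band_phase_grid()) {
  stopifnot(inherits(sg, "lv_spectrogram"), inherits(grid, "band_phase_grid"))
  if (max(vapply(grid$bands, `[`, numeric(1), 2)) > max(sg$freqs) + 1e-9)
    stopf("band grid exceeds the spectrogram's frequency axis")
  phase_frames <- list(
    inhale = in_intervals(sg$times, lm$inhale_intervals),
    exhale = in_intervals(sg$times, lm$exhale_intervals),
    full = rep(TRUE, length(sg$times))
  )
  out <- c()
  for (band in grid$bands) {
    fsel <- sg$freqs >= band[1] & sg$freqs < band[2]
    cell <- function(frames) {
      if (!any(frames) || !any(fsel)) return(NA_real_)
      mean(sg$power[fsel, frames, drop = FALSE])
    }
    for (ph in grid$phases)
      out[sprintf("%s_%s", band_label(band), ph)] <- cell(phase_frames[[ph]])
    out[sprintf("%s_inh_exh_ratio", band_label(band))] <-
      cell(phase_frames$inhale) / cell(phase_frames$exhale)
  }
  out
}

# all features of a single buffer from detected landmarks
buffer_features <- function(b, config) {
  lm <- detect_landmarks(b, hp_cutoff = config$hp_cutoff,
                         lp_cutoff = config$lp_cutoff,
                         min_separation_ms = config$min_separation_ms,
                         threshold_factor = config$threshold_factor,
                         smooth_ms = config$smooth_ms)
  if (!lm$quality_ok) return(NULL)
  td <- time_domain_features(b, lm, hp_cutoff = config$hp_cutoff,
                             smooth_ms = config$smooth_ms)
  if (!attr(td, "quality_ok")) return(NULL)
  sg <- compute_spectrogram(b, window_s = config$window_s,
                            overlap_frac = config$overlap_frac)
  fd <- frequency_domain_features(sg, lm, grid = config$grid)
  if (mean(is.na(fd)) >= 0.2) return(NULL)
  c(td, fd)
}

#' Assemble the per-measurement feature matrix for a cohort
#'
#' Splits each measurement into buffers, computes time and spectrogram
#' features on every quality-passing buffer, and aggregates them (mean by
#' default) into one row per measurement. Measurements with no usable buffer
#' are excluded and reported.
#'
#' @param measurements List of `vibration_measurement` (e.g. from
#'   [simulate_measurements()]).
#' @param cohort Cohort table with `subject_id` and `congested` (labels and
#'   covariates are carried through by subject id).
#' @param config A [pipeline_config()].
#' @return A list with `features` (data.frame: `measurement_id`, `subject_id`,
#'   `label`, then feature columns in deterministic order), `feature_names`,
#'   and `excluded` (character vector of dropped measurement ids).
#' @export
assemble_feature_matrix <- function(measurements, cohort, config = pipeline_config()) {
  agg <- if (identical(config$aggregate, "median")) {
    function(M) apply(M, 2, stats::median, na.rm = TRUE)
  } else {
    function(M) colMeans(M, na.rm = TRUE)
  }
  rows <- list(); excluded <- character(0)
  for (m in measurements) {
    bufs <- split_buffers(m, buffer_s = min(config$buffer_s, length(m$samples) / m$fs),
                          step_s = config$step_s)
    feats <- Filter(Negate(is.null), lapply(bufs, buffer_features, config = config))
    if (length(feats) == 0) {
      excluded <- c(excluded, m$measurement_id)
      next
    }
    v <- agg(do.call(rbind, feats))
    v[is.nan(v)] <- NA_real_
    rows[[m$measurement_id]] <- v
  }
  if (length(rows) == 0) stopf("no measurement produced a usable buffer")
  X <- do.call(rbind, rows)
  sid <- vapply(measurements[rownames(X)], `[[`, character(1), "subject_id")
  lab <- cohort$congested[match(sid, cohort$subject_id)]
  features <- data.frame(measurement_id = rownames(X), subject_id = sid,
                         label = lab, X, stringsAsFactors = FALSE,
                         row.names = NULL, check.names = FALSE)
  list(features = features, feature_names = colnames(X), excluded = excluded)
}

#' Median imputation learned on training data
#'
#' Computes per-column medians of a training feature matrix; [apply_imputation()]
#' fills missing cells (only) with those medians, so applying it to the matrix
#' it was learned on never changes a non-missing value.
#'
#' @param X Numeric matrix (training features).
#' @return Named numeric vector of column medians (class `lv_imputer`).
#' @export
fit_imputation <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  structure(med, class = "lv_imputer")
}

#' @rdname fit_imputation
#' @param imputer Result of [fit_imputation()].
#' @export
apply_imputation <- function(X, imputer) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) {
      nm <- colnames(X)[j]
      X[nas, j] <- if (!is.null(nm) && nm %in% names(imputer)) imputer[[nm]] else imputer[[j]]
    }
  }
  X
}
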