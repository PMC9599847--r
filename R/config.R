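#' Pipeline configuration
#'
#' Collects every tunable of the analysis stages with its default: buffer
#' splitting, filter cutoffs, landmark detection, spectrogram and band grid,
#' boosting rounds, NA-zone bound, cross-validation, bootstrap and reporting
#' choices. Validated as a whole before any stage runs.
#'
#' @param buffer_s,step_s Buffer length and hop, s.
#' @param hp_cutoff High-pass cutoff for heart sounds, Hz.
#' @param lp_cutoff Low-pass cutoff for the respiration wave, Hz.
#' @param min_separation_ms Peak refractory period, ms.
#' @param threshold_factor Envelope threshold as a multiple of its median.
#' @param smooth_ms Envelope smoothing window, ms.
#' @param window_s,overlap_frac Spectrogram window and overlap.
#' @param grid A [band_phase_grid()].
#' @param aggregate Per-measurement aggregation over buffers: `"mean"` or
#'   `"median"`.
#' @param n_rounds AdaBoost rounds T.
#' @param max_na_frac Largest tolerated inconclusive fraction.
#' @param k Cross-validation folds.
#' @param n_boot Bootstrap resamples for confidence intervals.
#' @param prevalence External prevalence for predictive values.
#' @param na_policy `"exclude"` drops inconclusives from the confusion
#'   counts; `"count_as_error"` charges them against their true class.
#' @param seed Seed for fold assignment and bootstrap.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(buffer_s = 60, step_s = 30,
                            hp_cutoff = 15, lp_cutoff = 1,
                            min_separation_ms = 200, threshold_factor = 3,
                            smooth_ms = 20, window_s = 2.0, overlap_frac = 0.75,
                            grid = band_phase_grid(), aggregate = c("mean", "median"),
                            n_rounds = 50, max_na_frac = 0.05,
                            k = 10, n_boot = 1000, prevalence = 0.32,
                            na_policy = c("exclude", "count_as_error"),
                            seed = 1) {
  aggregate <- match.arg(aggregate)
  na_policy <- match.arg(na_policy)
  check_scalar(buffer_s, "buffer_s", 0, open_lo = TRUE)
  check_scalar(step_s, "step_s", 0, open_lo = TRUE)
  check_scalar(max_na_frac, "max_na_frac", 0, 1, open_hi = TRUE)
  check_scalar(prevalence, "prevalence", 0, 1, TRUE, TRUE)
  check_scalar(k, "k", 2)
  check_scalar(n_rounds, "n_rounds", 1)
  stopifnot(inherits(grid, "band_phase_grid"))
  structure(as.list(environment()), class = "pipeline_config")
}
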