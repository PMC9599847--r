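#' Covariate distribution configuration for synthetic cohorts
#'
#' Describes how subject-level covariates are drawn, separately for congested
#' cases and non-congested controls. Defaults emulate a heart-failure cohort in
#' which cases are older and heavier. The acoustically active conditions
#' (murmur-producing valvular disorder, wheeze-producing respiratory disease)
#' default to label-independent population rates so that a zero congestion
#' effect leaves the case and control signal distributions identical; a
#' case/control shift in those rates can be configured explicitly when that
#' identity is not wanted.
#'
#' @param age_mean,age_sd Numeric length-2 vectors `c(control, case)`, years.
#' @param bmi_mean,bmi_sd Numeric length-2 vectors, kg/m^2.
#' @param male_prob Probability of male sex, `c(control, case)`.
#' @param hf_history_prob Probability of a heart-failure history.
#' @param respiratory_prob Probability of an ongoing respiratory condition
#'   (COPD, asthma and similar), which adds a wheeze component to the signal.
#' @param valvular_prob Probability of a valvular disorder of any grade, which
#'   adds a systolic murmur component.
#' @param extra_measurement_prob Probability that a subject contributes one
#'   additional measurement beyond the base count.
#' @return A list of class `covariate_config`.
#' @export
covariate_config <- function(age_mean = c(65, 73), age_sd = c(15, 12),
                             bmi_mean = c(28, 29), bmi_sd = c(5, 6),
                             male_prob = c(0.60, 0.71),
                             hf_history_prob = c(0.60, 0.77),
                             respiratory_prob = c(0.15, 0.15),
                             valvular_prob = c(0.40, 0.40),
                             extra_measurement_prob = 0.2) {
  cfg <- list(age_mean = age_mean, age_sd = age_sd, bmi_mean = bmi_mean,
              bmi_sd = bmi_sd, male_prob = male_prob,
              hf_history_prob = hf_history_prob,
              respiratory_prob = respiratory_prob,
              valvular_prob = valvular_prob,
              extra_measurement_prob = extra_measurement_prob)
  for (nm in c("age_mean", "age_sd", "bmi_mean", "bmi_sd", "male_prob",
               "hf_history_prob", "respiratory_prob", "valvular_prob"))
    if (length(cfg[[nm]]) != 2L) stopf("'%s' must be length 2 (control, case)", nm)
  check_scalar(extra_measurement_prob, "extra_measurement_prob", 0, 1)
  structure(cfg, class = "covariate_config")
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_subjects` subject records with a congestion label and covariates.
#' `round(n_subjects * case_fraction)` subjects are labeled congested;
#' covariates come from [covariate_config()], with case/control shifts so the
#' cohort shows the usual imbalances (older, heavier cases with more valvular
#' disease). Fully deterministic given `seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param case_fraction Fraction of congested subjects in `[0, 1]`.
#' @param measurements_per_subject Base number of measurements per subject;
#'   each subject gains one extra with probability
#'   `covariates$extra_measurement_prob`.
#' @param covariates A [covariate_config()].
#' @param seed Integer seed.
#' @return A `data.frame` with one row per subject: `subject_id`, `congested`,
#'   `age`, `sex`, `bmi`, `heart_failure_history`, `respiratory_condition`,
#'   `valvular_disorder`, `n_measurements`.
#' @examples
#' cohort <- generate_cohort(20, 0.5, seed = 1)
#' table(cohort$congested)
#' @export
generate_cohort <- function(n_subjects, case_fraction,
                            measurements_per_subject = 1,
                            covariates = covariate_config(), seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 2) stopf("'n_subjects' must be >= 2")
  check_scalar(case_fraction, "case_fraction", 0, 1)
  if (measurements_per_subject < 1) stopf("'measurements_per_subject' must be >= 1")
  n_subjects <- as.integer(n_subjects)
  n_cases <- as.integer(round(n_subjects * case_fraction))
  if (case_fraction > 0 && case_fraction < 1 && (n_cases == 0L || n_cases == n_subjects))
    stopf("requested both classes but rounding left one empty; adjust n_subjects or case_fraction")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  congested <- c(rep(TRUE, n_cases), rep(FALSE, n_subjects - n_cases))
  grp <- ifelse(congested, 2L, 1L) # index into (control, case) parameter pairs
  cc <- covariates
  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_subjects)),
    congested = congested,
    age = pmax(18, stats::rnorm(n_subjects, cc$age_mean[grp], cc$age_sd[grp])),
    sex = ifelse(stats::runif(n_subjects) < cc$male_prob[grp], "male", "female"),
    bmi = pmax(15, stats::rnorm(n_subjects, cc$bmi_mean[grp], cc$bmi_sd[grp])),
    heart_failure_history = stats::runif(n_subjects) < cc$hf_history_prob[grp],
    respiratory_condition = stats::runif(n_subjects) < cc$respiratory_prob[grp],
    valvular_disorder = stats::runif(n_subjects) < cc$valvular_prob[grp],
    n_measurements = as.integer(measurements_per_subject +
      (stats::runif(n_subjects) < cc$extra_measurement_prob)),
    stringsAsFactors = FALSE
  )
  cohort
}

# save/restore the global RNG so generators are pure given their seed argument
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
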