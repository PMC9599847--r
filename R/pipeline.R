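# end-to-end orchestration: the R surface behind the command-line front-end
# (inst/cli/lungvib)

#' Read a run configuration file
#'
#' YAML (or JSON, which YAML subsumes) with two optional blocks: `signal`
#' (arguments of [signal_model_config()]) and `pipeline` (arguments of
#' [pipeline_config()]), plus optional top-level `n_subjects`,
#' `case_fraction`, `seed`. Unknown keys are rejected so typos fail fast.
#'
#' @param path Config file path; `NULL` gives all defaults.
#' @return A list: `signal` config, `pipeline` config, `n_subjects`,
#'   `case_fraction`, `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("signal", "pipeline", "n_subjects", "case_fraction", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stopf("unknown config keys: %s", paste(extra, collapse = ", "))
  seed <- raw$seed %||% 1
  sig_args <- raw$signal %||% list()
  if (is.null(sig_args$seed)) sig_args$seed <- seed
  pip_args <- raw$pipeline %||% list()
  if (is.null(pip_args$seed)) pip_args$seed <- seed
  if (!is.null(pip_args$grid)) pip_args$grid <- do.call(band_phase_grid, pip_args$grid)
  list(signal = do.call(signal_model_config, sig_args),
       pipeline = do.call(pipeline_config, pip_args),
       n_subjects = raw$n_subjects %||% 100,
       case_fraction = raw$case_fraction %||% 0.5,
       seed = seed)
}

#' Simulate and persist a synthetic cohort
#'
#' Writes `cohort.csv` (one row per measurement: subject id, measurement id,
#' label, covariates, signal path), per-measurement signal CSVs with JSON
#' sidecars and ground-truth landmark JSONs under `signals/`, and a
#' `manifest.json` with md5 checksums of every file.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A list as returned by [read_run_config()] (or `NULL` for
#'   defaults).
#' @return Invisibly, the manifest as a data.frame.
#' @export
cmd_simulate <- function(out_dir, config = NULL) {
  cfg <- config %||% read_run_config(NULL)
  dir.create(file.path(out_dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg$n_subjects, cfg$case_fraction, seed = cfg$seed)
  measurements <- simulate_measurements(cohort, cfg$signal)
  rows <- lapply(measurements, function(m) {
    path <- write_signal_csv(m, file.path(out_dir, "signals"))
    s <- cohort[cohort$subject_id == m$subject_id, ]
    data.frame(subject_id = m$subject_id, measurement_id = m$measurement_id,
               label = s$congested, age = s$age, sex = s$sex, bmi = s$bmi,
               heart_failure = s$heart_failure_history,
               respiratory_condition = s$respiratory_condition,
               valvular_disorder = s$valvular_disorder,
               signal_path = file.path("signals", basename(path)),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "cohort.csv"), row.names = FALSE)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"), digits = NA)
  invisible(manifest)
}

#' Load a persisted cohort directory
#'
#' @param cohort_dir Directory written by [cmd_simulate()].
#' @return A list: `cohort` (subject-level table), `table` (per-measurement
#'   table), `measurements`.
#' @export
load_cohort_dir <- function(cohort_dir) {
  tab <- utils::read.csv(file.path(cohort_dir, "cohort.csv"), stringsAsFactors = FALSE)
  measurements <- lapply(file.path(cohort_dir, tab$signal_path), read_signal_csv)
  names(measurements) <- tab$measurement_id
  cohort <- unique(data.frame(subject_id = tab$subject_id, congested = tab$label,
                              age = tab$age, sex = tab$sex, bmi = tab$bmi,
                              heart_failure_history = tab$heart_failure,
                              respiratory_condition = tab$respiratory_condition,
                              valvular_disorder = tab$valvular_disorder,
                              stringsAsFactors = FALSE))
  list(cohort = cohort, table = tab, measurements = measurements)
}

#' Run the full analysis pipeline on a cohort
#'
#' Landmarks, features, grouped cross-validation, diagnostic report with
#' bootstrap intervals; also trains a final calibrated model on all data.
#' In-memory twin of the `run` CLI subcommand.
#'
#' @param measurements List of `vibration_measurement`.
#' @param cohort Subject-level cohort table.
#' @param config A [pipeline_config()].
#' @return A list: `features` ([assemble_feature_matrix()] result),
#'   `cv_scores`, `report`, `model`.
#' @export
run_pipeline <- function(measurements, cohort, config = pipeline_config()) {
  fm <- assemble_feature_matrix(measurements, cohort, config)
  cv <- cross_validated_scores(fm$features, config)
  report <- diagnostic_report(cv, config)
  fcols <- fm$feature_names
  X <- as.matrix(fm$features[, fcols, drop = FALSE])
  imp <- fit_imputation(X)
  X <- apply_imputation(X, imp)
  fit <- train_adaboost(X, fm$features$label, n_rounds = config$n_rounds)
  model <- fit$model
  s <- score_measurements(model, X)
  model$operating_threshold <- select_operating_point(s, fm$features$label)
  model$na_zone <- calibrate_na_zone(s, fm$features$label, model$operating_threshold,
                                     max_na_frac = config$max_na_frac)
  list(features = fm, cv_scores = cv, report = report, model = model)
}

#' Pipeline CLI subcommand: run
#'
#' @param cohort_dir Directory from [cmd_simulate()].
#' @param out_dir Output directory.
#' @param config A [read_run_config()] list or `NULL`.
#' @return Invisibly, the [run_pipeline()] result.
#' @export
cmd_run <- function(cohort_dir, out_dir, config = NULL) {
  cfg <- config %||% read_run_config(NULL)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loaded <- load_cohort_dir(cohort_dir)
  res <- run_pipeline(loaded$measurements, loaded$cohort, cfg$pipeline)
  write_feature_csv(res$features, file.path(out_dir, "features.csv"))
  utils::write.csv(res$cv_scores, file.path(out_dir, "cv_scores.csv"), row.names = FALSE)
  model_to_json(res$model, file.path(out_dir, "model.json"))
  write_report(res$report, file.path(out_dir, "report.json"),
               file.path(out_dir, "report.md"))
  if (length(res$features$excluded))
    warning(sprintf("excluded measurements with no usable buffer: %s",
                    paste(res$features$excluded, collapse = ", ")))
  invisible(res)
}

#' Pipeline CLI subcommand: duration sweep
#'
#' @param cohort_dir Directory from [cmd_simulate()].
#' @param out_dir Output directory for `sweep.csv`.
#' @param config A [read_run_config()] list or `NULL`.
#' @param durations Durations, s.
#' @return Invisibly, the sweep table.
#' @export
cmd_sweep <- function(cohort_dir, out_dir, config = NULL, durations = seq(30, 120, by = 5)) {
  cfg <- config %||% read_run_config(NULL)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loaded <- load_cohort_dir(cohort_dir)
  sweep <- duration_sweep(loaded$measurements, loaded$cohort, cfg$pipeline, durations)
  utils::write.csv(sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  invisible(sweep)
}

#' Pipeline CLI subcommand: covariate screen
#'
#' Reads `cv_scores.csv` from a `run` output directory and the cohort table,
#' and writes `covariates.csv` with one test per covariate.
#'
#' @param cohort_dir Directory from [cmd_simulate()].
#' @param run_dir Directory from [cmd_run()].
#' @param out_path Output CSV path (default `covariates.csv` in `run_dir`).
#' @return Invisibly, the covariate table.
#' @export
cmd_covariates <- function(cohort_dir, run_dir,
                           out_path = file.path(run_dir, "covariates.csv")) {
  cv_path <- file.path(run_dir, "cv_scores.csv")
  if (!file.exists(cv_path)) stopf("missing run artifact: %s", cv_path)
  cv <- utils::read.csv(cv_path, stringsAsFactors = FALSE)
  tab <- utils::read.csv(file.path(cohort_dir, "cohort.csv"), stringsAsFactors = FALSE)
  idx <- match(cv$measurement_id, tab$measurement_id)
  if (anyNA(idx)) stopf("cv_scores and cohort tables do not align")
  covs <- tab[idx, c("age", "sex", "bmi", "heart_failure",
                     "respiratory_condition", "valvular_disorder")]
  out <- covariate_effect_table(cv, covs)
  utils::write.csv(out, out_path, row.names = FALSE)
  invisible(out)
}
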