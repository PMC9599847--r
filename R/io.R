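# plain-text I/O: one-column CSV signals with JSON sidecars, landmark JSON,
# cohort/feature/report tables

#' Write and read a vibration signal as one-column CSV
#'
#' The signal goes to `<measurement_id>.csv` (column `sample`) with a JSON
#' sidecar `<measurement_id>.json` carrying `fs` and ids; ground-truth
#' landmarks, when present, go to `<measurement_id>_landmarks.json`.
#'
#' @param m A `vibration_measurement`.
#' @param dir Output directory.
#' @return (write) the data-file path, invisibly; (read) the measurement.
#' @export
write_signal_csv <- function(m, dir) {
  stopifnot(inherits(m, "vibration_measurement"))
  path <- file.path(dir, paste0(m$measurement_id, ".csv"))
  utils::write.csv(data.frame(sample = m$samples), path, row.names = FALSE)
  jsonlite::write_json(list(fs = m$fs, subject_id = m$subject_id,
                            measurement_id = m$measurement_id),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  if (!is.null(m$truth_landmarks))
    write_landmarks_json(m$truth_landmarks, sub("\\.csv$", "_landmarks.json", path))
  invisible(path)
}

#' @rdname write_signal_csv
#' @param path Path of the signal CSV; the sidecar is found next to it.
#' @export
read_signal_csv <- function(path) {
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  lm_path <- sub("\\.csv$", "_landmarks.json", path)
  structure(list(subject_id = side$subject_id,
                 measurement_id = side$measurement_id,
                 fs = side$fs,
                 samples = utils::read.csv(path)$sample,
                 truth_landmarks = if (file.exists(lm_path)) read_landmarks_json(lm_path)),
            class = "vibration_measurement")
}

#' Landmark JSON round-trip
#'
#' Serializes a [landmark_set()] (times in seconds; intervals as arrays of
#' `[start, end]` pairs), matching the generator's ground-truth schema.
#'
#' @param lm A `landmark_set`.
#' @param path File path.
#' @export
write_landmarks_json <- function(lm, path) {
  iv_list <- function(iv) lapply(seq_len(nrow(iv)), function(i) as.numeric(iv[i, ]))
  jsonlite::write_json(list(s1_times = lm$s1_times, s2_times = lm$s2_times,
                            inhale_intervals = iv_list(lm$inhale_intervals),
                            exhale_intervals = iv_list(lm$exhale_intervals)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(s1_times = as.numeric(unlist(obj$s1_times)),
               s2_times = as.numeric(unlist(obj$s2_times)),
               inhale_intervals = obj$inhale_intervals,
               exhale_intervals = obj$exhale_intervals)
}

#' Dump a spectrogram as an inspectable CSV matrix
#'
#' First column holds the frequency axis (Hz); the header row holds the frame
#' centers (s); body cells are spectral power.
#'
#' @param sg An `lv_spectrogram`.
#' @param path CSV path.
#' @export
write_spectrogram_csv <- function(sg, path) {
  stopifnot(inherits(sg, "lv_spectrogram"))
  df <- data.frame(freq_hz = sg$freqs, sg$power, check.names = FALSE)
  colnames(df)[-1] <- sprintf("t_%g", sg$times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the feature matrix with its schema
#'
#' @param fm Result of [assemble_feature_matrix()].
#' @param path CSV path; a `<path>.schema.json` listing the deterministic
#'   column order is written beside it.
#' @export
write_feature_csv <- function(fm, path) {
  utils::write.csv(fm$features, path, row.names = FALSE)
  jsonlite::write_json(list(meta_columns = c("measurement_id", "subject_id", "label"),
                            feature_columns = fm$feature_names,
                            excluded = fm$excluded),
                       paste0(path, ".schema.json"), digits = NA)
  invisible(path)
}

#' Write a diagnostic report as JSON and Markdown
#'
#' @param report A [diagnostic_report()].
#' @param json_path,md_path Output paths (either may be `NULL` to skip).
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path)) {
    obj <- unclass(report)
    obj$counts <- unclass(obj$counts)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  if (!is.null(md_path)) {
    fmt <- function(nm, label) {
      v <- report[[nm]]
      sprintf("| %s | %.3f (%.3f, %.3f) |", label, v["estimate"], v["lo"], v["hi"])
    }
    lines <- c("| Variable | Point Estimate (95% CI) |", "|---|---|",
               fmt("sensitivity", "Sensitivity"),
               fmt("specificity", "Specificity"),
               fmt("balanced_accuracy", "Balanced accuracy"),
               fmt("auc", "AUC"),
               fmt("ppv_sample", "PPV (sample prevalence)"),
               fmt("npv_sample", "NPV (sample prevalence)"),
               fmt("ppv_at_p", sprintf("PPV (%.0f%% prevalence)", 100 * report$prevalence)),
               fmt("npv_at_p", sprintf("NPV (%.0f%% prevalence)", 100 * report$prevalence)),
               fmt("plr", "PLR"), fmt("nlr", "NLR"),
               sprintf("| NA fraction | %.3f |", report$na_fraction))
    writeLines(lines, md_path)
  }
  invisible(report)
}
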