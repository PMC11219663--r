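#' Read and write raw recording CSVs
#'
#' The recording interchange format has the exact header
#' `time_s,icp_mmhg,map_mmhg,amp_mmhg` with monotonically increasing time.
#' Unknown extra columns are ignored with a warning; a missing required
#' column or non-monotone time is a parse error. Round-tripping preserves
#' values to full double precision.
#'
#' @param path File path.
#' @return `read_recording_csv()` returns a recording tibble (`time_s`,
#'   `icp`, `map`, `amp`); `write_recording_csv()` returns `path`
#'   invisibly.
#' @export
read_recording_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("time_s", "icp_mmhg", "map_mmhg", "amp_mmhg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("recording CSV lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    warn(sprintf("ignoring unknown column(s): %s", paste(extra, collapse = ", ")))
  }
  bad <- which(!is.finite(df$time_s))
  if (length(bad) > 0) {
    abort(sprintf("malformed time values at line(s): %s",
                  paste(head(bad + 1, 5), collapse = ", ")))
  }
  if (any(diff(df$time_s) <= 0)) {
    abort(sprintf("time column not strictly increasing (first violation at line %d)",
                  which(diff(df$time_s) <= 0)[1] + 2))
  }
  tibble(time_s = df$time_s, icp = df$icp_mmhg, map = df$map_mmhg, amp = df$amp_mmhg)
}

#' @rdname read_recording_csv
#' @param rec Recording tibble (`time_s`, `icp`, `map`, `amp`).
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(is.data.frame(rec), all(c("time_s", "icp", "map", "amp") %in% names(rec)))
  out <- tibble(time_s = rec$time_s, icp_mmhg = rec$icp,
                map_mmhg = rec$map, amp_mmhg = rec$amp)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write cohort ground-truth and baseline table
#'
#' @param cohort Cohort tibble from [sim_cohort()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("patient_id", "age", "sex", "gcs", "is_ih", "is_sih", "onset_hours")
  readr::write_csv(cohort[, intersect(cols, names(cohort))], path, progress = FALSE)
  invisible(path)
}

#' Read and write study configuration as YAML
#'
#' Serializes a [study_config()] to a structured text file and rebuilds a
#' validated config from it; unknown keys are rejected.
#'
#' @param config A [study_config()].
#' @param path File path.
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` returns a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- lapply(unclass(config), function(v) if (is.list(v)) lapply(unclass(v), identity) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("sim", "rf", "complexity", "feature_window_h", "epoch_s", "smooth_span",
             "index_window_epochs", "ih_threshold", "ih_min", "sih_min",
             "min_record_h", "train_fraction", "seed")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  reconstruct <- function(vals, fun) {
    unknown <- setdiff(names(vals), names(formals(fun)))
    if (length(unknown) > 0) {
      abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    }
    do.call(fun, lapply(vals, function(v) if (is.list(v)) unlist(v) else v))
  }
  args <- x[setdiff(names(x), c("sim", "rf", "complexity"))]
  args$sim <- reconstruct(x$sim %||% list(), sim_config)
  args$rf <- reconstruct(x$rf %||% list(), rf_config)
  args$complexity <- reconstruct(x$complexity %||% list(), complexity_params)
  do.call(study_config, args)
}

#' Write the cohort feature table
#'
#' Emits the canonical header
#' `patient_id,age,sex,gcs,icp_m,cpp_m,prx_m,rap_m,icp_sampen,cpp_sampen,icp_lzc,cpp_lzc,ih,sih`.
#'
#' @param features Feature table from [build_feature_table()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  cols <- c("patient_id", feature_names(), "ih", "sih")
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0) {
    abort(sprintf("feature table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(features[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write an epoch series
#'
#' Emits `epoch_idx,t_mid_s,icp,map,cpp,amp,valid`.
#'
#' @param es Epoch series from [resample_epochs()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(es, path) {
  cols <- c("epoch_idx", "t_mid_s", "icp", "map", "cpp", "amp", "valid")
  readr::write_csv(es[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write per-patient outcome labels
#'
#' Emits `patient_id,ih,sih,time_to_ih_h,time_to_sih_h,excluded`.
#'
#' @param labels Tibble of [label_outcomes()] rows with a `patient_id` column.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  cols <- c("patient_id", "ih", "sih", "time_to_ih_h", "time_to_sih_h", "excluded")
  readr::write_csv(labels[, intersect(cols, names(labels))], path, progress = FALSE)
  invisible(path)
}
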