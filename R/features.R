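#' Feature names used by the prediction models
#'
#' The 11 candidate predictors: 3 baseline covariates, 4 linear features
#' (6-h means of ICP, CPP, PRx, RAP) and 4 nonlinear complexity features.
#' @return Character vector.
#' @export
feature_names <- function() {
  c("age", "sex", "gcs", "icp_m", "cpp_m", "prx_m", "rap_m",
    "icp_sampen", "cpp_sampen", "icp_lzc", "cpp_lzc")
}

#' Extract the per-patient feature vector
#'
#' Runs the full feature pipeline on the first `feature_window_h` hours of a
#' raw recording: 12-s epoch resampling, span-4 trailing smoothing, window
#' extraction, 6-h means of ICP and CPP, moving-correlation indices (PRx,
#' RAP) and their means, and the four nonlinear complexity features. Only the
#' feature window is ever touched, so no outcome-period information can leak
#' into the features.
#'
#' @param rec Raw recording tibble (`time_s`, `icp`, `map`, `amp`).
#' @param baseline Named list or one-row data frame with `age`, `sex`
#'   (0 = female, 1 = male), `gcs`.
#' @param feature_window_h Feature window length in hours (default 6).
#' @param epoch_s,smooth_span Preprocessing parameters (defaults 12 s, 4).
#' @param index_window_epochs Moving-correlation window for PRx/RAP (default
#'   30 epochs = 6 min).
#' @param params [complexity_params()] for the nonlinear features.
#' @return One-row tibble with the columns of [feature_names()].
#' @export
featurize_patient <- function(rec, baseline, feature_window_h = 6, epoch_s = 12,
                              smooth_span = 4, index_window_epochs = 30,
                              params = complexity_params()) {
  for (f in c("age", "sex", "gcs")) {
    if (is.null(baseline[[f]]) || is.na(baseline[[f]])) {
      abort(sprintf("missing baseline field `%s`", f))
    }
  }
  es <- resample_epochs(rec, epoch_s)
  keep_attr <- attr(es, "epoch_s")
  es <- smooth_epochs(es, smooth_span)
  attr(es, "epoch_s") <- keep_attr
  e6 <- extract_window(es, 0, feature_window_h)
  cx <- complexity_features(e6, params)
  tibble(
    age = as.numeric(baseline$age),
    sex = as.numeric(baseline$sex),
    gcs = as.numeric(baseline$gcs),
    icp_m = window_mean(e6$icp[e6$valid]),
    cpp_m = window_mean(e6$cpp[e6$valid]),
    prx_m = window_mean(prx(e6, index_window_epochs)),
    rap_m = window_mean(rap(e6, index_window_epochs)),
    icp_sampen = cx$icp_sampen,
    cpp_sampen = cx$cpp_sampen,
    icp_lzc = cx$icp_lzc,
    cpp_lzc = cx$cpp_lzc
  )
}

#' Build the cohort feature table
#'
#' Applies the inclusion filters, labels outcomes over the post-window
#' monitoring period, and extracts the 11-feature vector for every included
#' patient. Rows with missing features are kept (the modeling stage imputes
#' by training-set medians).
#'
#' @param cohort Cohort tibble with `patient_id`, `age`, `sex`, `gcs` and a
#'   `recording` list-column ([sim_cohort()] output or equivalent).
#' @inheritParams featurize_patient
#' @param ih_threshold,ih_min,sih_min,min_record_h Outcome-definition and
#'   inclusion parameters (defaults 22 mmHg, 5 min, 60 min, 18 h).
#' @return Feature tibble with `patient_id`, the 11 features, and logical
#'   outcomes `ih`, `sih`; one row per included patient. The exclusion table
#'   is attached as attribute `"exclusions"`.
#' @export
build_feature_table <- function(cohort, feature_window_h = 6, epoch_s = 12,
                                smooth_span = 4, index_window_epochs = 30,
                                params = complexity_params(),
                                ih_threshold = 22, ih_min = 5, sih_min = 60,
                                min_record_h = 18) {
  stopifnot(is.data.frame(cohort), all(c("patient_id", "recording") %in% names(cohort)))
  if (anyDuplicated(cohort$patient_id)) abort("duplicated patient_id in cohort")
  if (!"included" %in% names(cohort)) {
    cohort <- apply_inclusion_filters(cohort, min_record_h = min_record_h,
                                      threshold_mmHg = ih_threshold,
                                      feature_window_h = feature_window_h)
  }
  excl <- cohort[!cohort$included, c("patient_id", "reason")]
  inc <- cohort[cohort$included, , drop = FALSE]
  if (nrow(inc) == 0) abort("all patients excluded")
  rows <- map(seq_len(nrow(inc)), function(i) {
    rec <- inc$recording[[i]]
    feats <- featurize_patient(rec, inc[i, c("age", "sex", "gcs")],
                               feature_window_h, epoch_s, smooth_span,
                               index_window_epochs, params)
    lab <- label_outcomes(resample_epochs(rec, epoch_s),
                          feature_window_h = feature_window_h,
                          threshold_mmHg = ih_threshold,
                          ih_min_duration_min = ih_min,
                          sih_min_duration_min = sih_min,
                          min_record_h = min_record_h)
    dplyr::bind_cols(tibble(patient_id = inc$patient_id[i]), feats,
                     lab[, c("ih", "sih", "time_to_ih_h", "time_to_sih_h")])
  })
  out <- list_rbind(rows)
  n_miss <- sum(is.na(out[, feature_names()]))
  if (n_miss > 0) {
    rlang::inform(sprintf("feature table: %d missing feature values across %d patients",
                          n_miss, nrow(out)))
  }
  attr(out, "exclusions") <- excl
  out
}
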