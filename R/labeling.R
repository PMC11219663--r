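#' Detect threshold-duration episodes of intracranial hypertension
#'
#' Scans an epoch-level ICP series for maximal runs of consecutive epochs with
#' ICP strictly above the threshold, and keeps runs whose duration is strictly
#' greater than `min_duration_min`. Both inequalities are strict, so a run of
#' exactly 5 min at exactly 22 mmHg qualifies for neither. Invalid (`NA`)
#' epochs break a run; no gap tolerance is applied — a single sub-threshold
#' epoch ends an episode.
#'
#' @param icp_epochs Numeric vector of epoch-averaged ICP (mmHg); `NA` marks
#'   invalid epochs.
#' @param threshold_mmHg Episode threshold (default 22 mmHg, the guideline
#'   treatment threshold).
#' @param min_duration_min Minimum duration in minutes a run must *exceed* to
#'   count (5 for IH, 60 for severe IH).
#' @param epoch_s Epoch length in seconds (default 12).
#' @return Tibble with one row per episode: `start_epoch`, `end_epoch`
#'   (inclusive indices), `duration_min`, `peak_icp`. Zero rows when no run
#'   qualifies.
#' @export
detect_episodes <- function(icp_epochs, threshold_mmHg = 22, min_duration_min = 5,
                            epoch_s = 12) {
  if (!is_number(threshold_mmHg) || threshold_mmHg <= 0) abort("`threshold_mmHg` must be > 0")
  above <- !is.na(icp_epochs) & icp_epochs > threshold_mmHg
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * epoch_s / 60 > min_duration_min)
  tibble(
    start_epoch = starts[keep],
    end_epoch = ends[keep],
    duration_min = r$lengths[keep] * epoch_s / 60,
    peak_icp = map_dbl(which(keep), function(i) max(icp_epochs[starts[i]:ends[i]]))
  )
}

#' Label IH and severe-IH outcomes for one patient
#'
#' Applies the threshold-duration outcome definitions over the monitoring
#' period that follows the feature window: IH is ICP > 22 mmHg sustained for
#' more than 5 min, severe IH (SIH) for more than 1 h. Episodes are detected
#' on the unsmoothed epoch series over the whole recording; an episode counts
#' toward the outcome if any part of it lies after the feature window. Times
#' to event are measured from the end of the feature window to episode onset.
#'
#' @param es Epoch series for the full recording ([resample_epochs()] output,
#'   unsmoothed).
#' @param feature_window_h Length of the feature window in hours (default 6).
#' @param threshold_mmHg,ih_min_duration_min,sih_min_duration_min Outcome
#'   definition parameters (defaults 22 mmHg, 5 min, 60 min).
#' @param min_record_h Minimum recording length in hours (default 18); shorter
#'   recordings are flagged excluded and receive no label.
#' @return One-row tibble `ih`, `sih`, `time_to_ih_h`, `time_to_sih_h`,
#'   `excluded`.
#' @export
label_outcomes <- function(es, feature_window_h = 6, threshold_mmHg = 22,
                           ih_min_duration_min = 5, sih_min_duration_min = 60,
                           min_record_h = 18) {
  stopifnot(is.data.frame(es), all(c("t_mid_s", "icp") %in% names(es)))
  epoch_s <- attr(es, "epoch_s") %||% 12
  hours <- nrow(es) * epoch_s / 3600
  if (hours < min_record_h) {
    return(tibble(ih = NA, sih = NA, time_to_ih_h = NA_real_,
                  time_to_sih_h = NA_real_, excluded = TRUE))
  }
  ep <- detect_episodes(es$icp, threshold_mmHg, ih_min_duration_min, epoch_s)
  # keep episodes with any epoch after the feature window
  end_s <- es$t_mid_s[ep$end_epoch] + epoch_s / 2
  ep <- ep[end_s > feature_window_h * 3600, , drop = FALSE]
  first_time <- function(e) {
    if (nrow(e) == 0) return(NA_real_)
    onset_h <- (es$t_mid_s[e$start_epoch[1]] - epoch_s / 2) / 3600
    max(onset_h - feature_window_h, 0)
  }
  sih_ep <- ep[ep$duration_min > sih_min_duration_min, , drop = FALSE]
  tibble(
    ih = nrow(ep) > 0,
    sih = nrow(sih_ep) > 0,
    time_to_ih_h = first_time(ep),
    time_to_sih_h = first_time(sih_ep),
    excluded = FALSE
  )
}

#' Apply the cohort inclusion filters
#'
#' Reproduces the three-stage cohort filter: (a) recordings shorter than
#' `min_record_h` are excluded (`short_recording`); (b) recordings with more
#' than `max_invalid_frac` invalid epochs are excluded (`artifact`); (c)
#' patients with persistent early intracranial hypertension — first-6-h mean
#' ICP above the threshold AND more than 80% of first-6-h epochs above it —
#' are excluded (`early_persistent_ih`), because for them the event to be
#' predicted has already happened.
#'
#' @param cohort A cohort tibble with a `recording` list-column (one raw
#'   recording per patient, see [sim_cohort()]) and a `patient_id` column.
#' @param min_record_h Minimum recording hours (default 18).
#' @param max_invalid_frac Maximum tolerated fraction of invalid epochs
#'   (default 0.3).
#' @param threshold_mmHg Early-IH threshold (default 22).
#' @param feature_window_h Length of the early window screened for persistent
#'   IH (default 6 h).
#' @return The cohort with logical `included` and character `reason`
#'   (`NA` for included patients) columns added.
#' @export
apply_inclusion_filters <- function(cohort, min_record_h = 18, max_invalid_frac = 0.3,
                                    threshold_mmHg = 22, feature_window_h = 6) {
  stopifnot(is.data.frame(cohort), "recording" %in% names(cohort))
  if (nrow(cohort) == 0) abort("empty cohort")
  res <- map(cohort$recording, function(rec) {
    es <- resample_epochs(rec)
    epoch_s <- attr(es, "epoch_s")
    hours <- nrow(es) * epoch_s / 3600
    if (hours < min_record_h) return(list(included = FALSE, reason = "short_recording"))
    if (mean(!es$valid) > max_invalid_frac) return(list(included = FALSE, reason = "artifact"))
    e6 <- extract_window(es, 0, feature_window_h)
    icp6 <- e6$icp[e6$valid]
    if (length(icp6) > 0 && mean(icp6) > threshold_mmHg &&
        mean(icp6 > threshold_mmHg) > 0.8) {
      return(list(included = FALSE, reason = "early_persistent_ih"))
    }
    list(included = TRUE, reason = NA_character_)
  })
  cohort$included <- map_lgl(res, "included")
  cohort$reason <- purrr::map_chr(res, "reason")
  cohort
}
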