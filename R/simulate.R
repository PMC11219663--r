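#' Configuration for the synthetic TBI cohort simulator
#'
#' Defines the study conditions emulated by the generator. Group-effect
#' parameters are length-3 named vectors `(neg, ih, sih)` giving the value for
#' event-negative patients, patients with an intracranial hypertension (IH)
#' event only, and patients progressing to severe IH (SIH); effect directions
#' follow the published group contrasts (event-positive patients: higher ICP,
#' stronger ICP-MAP coupling, more irregular CPP, *less* irregular ICP, lower
#' GCS, higher age).
#'
#' @param n_patients Number of patients.
#' @param prevalence_ih Marginal probability of an IH event (default 0.623).
#' @param prevalence_sih_given_ih Probability that an IH patient progresses to
#'   SIH (default 30/43 = 0.698, so the marginal SIH fraction is 0.435).
#' @param record_hours Recording length in hours (>= 18; default 18).
#' @param sample_period_s Sampling period of the raw channels (default 1 s).
#' @param icp_baseline_mmHg Per-group mean baseline ICP, mmHg.
#' @param prx_coupling Per-group target coupling between the slow components
#'   of ICP and MAP, in `[-1, 1]`; controls PRx.
#' @param cpp_irregularity Per-group standard deviation (mmHg) of the
#'   MAP-specific AR(1) innovations; controls CPP sample entropy / LZ
#'   complexity.
#' @param icp_irregularity Per-group amplitude (mmHg) of ICP-specific slow-wave
#'   activity; lower in event-positive patients so that their ICP epoch series
#'   is more regular (lower ICP sample entropy / LZ complexity).
#' @param ih_onset_hours_range Interval (hours) from which planted episode
#'   onsets are drawn; must lie entirely after hour 6.
#' @param ih_duration_min_range,sih_duration_min_range Intervals (minutes)
#'   for planted episode durations; IH-only durations must exceed 5 min and
#'   stay below 60 min, SIH durations must exceed 60 min.
#' @param seed Master seed; per-patient substreams are derived from it by
#'   hashing the patient id, so cohorts are invariant to generation order.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 69,
                       prevalence_ih = 0.623,
                       prevalence_sih_given_ih = 30 / 43,
                       record_hours = 18,
                       sample_period_s = 1,
                       icp_baseline_mmHg = c(neg = 9, ih = 13, sih = 14.5),
                       prx_coupling = c(neg = 0.25, ih = 0.40, sih = 0.44),
                       cpp_irregularity = c(neg = 0.5, ih = 2.8, sih = 3.4),
                       icp_irregularity = c(neg = 0.5, ih = 0.22, sih = 0.2),
                       ih_onset_hours_range = c(7, 14),
                       ih_duration_min_range = c(8, 30),
                       sih_duration_min_range = c(70, 150),
                       seed = 1L) {
  grp <- function(x, name, lo = -Inf, hi = Inf) {
    if (length(x) == 1) x <- c(neg = x, ih = x, sih = x)
    if (length(x) != 3 || !all(is.finite(x)) || any(x < lo) || any(x > hi)) {
      abort(sprintf("`%s` must be 3 finite per-group values in [%g, %g]", name, lo, hi))
    }
    names(x) <- c("neg", "ih", "sih")
    x
  }
  if (!is_count(n_patients)) abort("`n_patients` must be a positive integer")
  for (p in c(prevalence_ih, prevalence_sih_given_ih)) {
    if (!is_number(p) || p < 0 || p > 1) abort("prevalences must lie in [0, 1]")
  }
  if (!is_number(record_hours) || record_hours < 18) abort("`record_hours` must be >= 18")
  if (!is_number(sample_period_s) || sample_period_s <= 0) abort("`sample_period_s` must be > 0")
  if (length(ih_onset_hours_range) != 2 || ih_onset_hours_range[1] <= 6 ||
      diff(ih_onset_hours_range) < 0) {
    abort("`ih_onset_hours_range` must lie entirely after hour 6")
  }
  if (ih_onset_hours_range[2] + max(sih_duration_min_range) / 60 + 0.25 > record_hours) {
    abort("planted episodes would not fit inside `record_hours`")
  }
  if (ih_duration_min_range[1] <= 5 || ih_duration_min_range[2] >= 60) {
    abort("`ih_duration_min_range` must lie in (5, 60) minutes")
  }
  if (sih_duration_min_range[1] <= 60) abort("`sih_duration_min_range` must exceed 60 minutes")
  structure(list(
    n_patients = as.integer(n_patients),
    prevalence_ih = prevalence_ih,
    prevalence_sih_given_ih = prevalence_sih_given_ih,
    record_hours = record_hours,
    sample_period_s = sample_period_s,
    icp_baseline_mmHg = grp(icp_baseline_mmHg, "icp_baseline_mmHg", 0, 25),
    prx_coupling = grp(prx_coupling, "prx_coupling", -1, 1),
    cpp_irregularity = grp(cpp_irregularity, "cpp_irregularity", 0),
    icp_irregularity = grp(icp_irregularity, "icp_irregularity", 0),
    ih_onset_hours_range = as.numeric(ih_onset_hours_range),
    ih_duration_min_range = as.numeric(ih_duration_min_range),
    sih_duration_min_range = as.numeric(sih_duration_min_range),
    seed = as.integer(seed)
  ), class = "sim_config")
}

severity_group <- function(is_ih, is_sih) {
  dplyr::case_when(is_sih ~ "sih", is_ih ~ "ih", TRUE ~ "neg")
}

# sum of three sinusoidal slow waves (periods 60-120 s), unit variance
slow_wave <- function(t) {
  periods <- runif(3, 60, 120)
  phases <- runif(3, 0, 2 * pi)
  amps <- runif(3, 0.5, 1)
  s <- rowSums(vapply(1:3, function(j) amps[j] * sin(2 * pi * t / periods[j] + phases[j]),
                      numeric(length(t))))
  s / sd(s)
}

ar1_noise <- function(n, innovation_sd, phi = 0.9) {
  as.numeric(stats::filter(rnorm(n, 0, innovation_sd), phi, method = "recursive"))
}

# standardized slow pressure-wave process: a long-timescale smooth drift
# (vasogenic trend) carrying most of the variance, plus 30-120 s B-waves
slow_process <- function(t, b_frac = 0.18) {
  drift <- ar1_noise(length(t), 1, phi = 0.9999)
  drift <- drift / sd(drift)
  sqrt(1 - b_frac^2) * drift + b_frac * slow_wave(t)
}

#' Simulate one patient recording
#'
#' Generates the three 1-Hz channels for a single patient: ICP as baseline +
#' slow vasogenic drift and B-wave oscillations + AR(1) noise + a steep
#' logistic ramp for the planted hypertensive episode; MAP sharing the ICP
#' slow component at the group coupling weight (which sets PRx) plus its own
#' slow component and AR(1) noise (whose scale sets CPP irregularity); AMP
#' derived from a compensatory-reserve state that rises with ICP. The first
#' 6 h never contain a qualifying episode, so simulated patients always pass
#' the early-persistent-IH exclusion filter. Deterministic given
#' `(config$seed, patient_id)`.
#'
#' @param config A [sim_config()] object.
#' @param patient_id Character id; hashed into the per-patient random
#'   substream.
#' @param outcome One-row data frame (or list) with `is_ih`, `is_sih`, and for
#'   event-positive patients `onset_hours` and `duration_min`.
#' @return Recording tibble `time_s`, `icp`, `map`, `amp`.
#' @export
sim_patient <- function(config, patient_id, outcome) {
  stopifnot(inherits(config, "sim_config"))
  is_ih <- isTRUE(as.logical(outcome$is_ih))
  is_sih <- isTRUE(as.logical(outcome$is_sih))
  if (is_sih && !is_ih) abort("inconsistent outcome: is_sih implies is_ih")
  g <- severity_group(is_ih, is_sih)
  dt <- config$sample_period_s
  n <- as.integer(round(config$record_hours * 3600 / dt))
  t <- (seq_len(n) - 1) * dt

  withr::with_seed(substream_seed(config$seed, patient_id), {
    base_icp <- config$icp_baseline_mmHg[[g]] + rnorm(1, 0, 1.5)
    drift <- ar1_noise(n, 1, phi = 0.9999)
    drift <- drift / sd(drift)
    b_frac <- 0.10
    s_shared <- sqrt(1 - b_frac^2) * drift + b_frac * slow_wave(t)
    s_map <- slow_process(t)
    rho <- config$prx_coupling[[g]]

    # slow shared/specific pressure waves plus a fast component whose scale is
    # the per-group irregularity knob (sets epoch-scale complexity)
    icp <- base_icp + 2 * s_shared +
      config$icp_irregularity[[g]] * slow_wave(t) +
      ar1_noise(n, 0.15, phi = 0.3)
    map <- 90 + rnorm(1, 0, 5) +
      4 * (rho * s_shared + sqrt(1 - rho^2) * s_map) +
      ar1_noise(n, config$cpp_irregularity[[g]], phi = 0.3)

    ramp <- rep(0, n)
    if (is_ih) {
      onset_h <- outcome$onset_hours
      dur_min <- outcome$duration_min
      if (!is_number(onset_h) || onset_h <= 6) {
        abort("configuration error: planted onset must lie after hour 6")
      }
      if (!is_number(dur_min) || dur_min <= 5) {
        abort("configuration error: planted duration must exceed 5 min")
      }
      if (onset_h + dur_min / 60 >= config$record_hours) {
        abort("configuration error: planted episode exceeds the recording")
      }
      plateau <- max(27, 29 + rnorm(1, 0, 1))
      h <- plateau - base_icp
      on_s <- onset_h * 3600
      off_s <- on_s + dur_min * 60
      # shift the logistic edges so ICP crosses the 22 mmHg threshold at the
      # planted onset/offset times, not a ramp-delay later
      tau <- 2
      d <- tau * stats::qlogis(min(max((22.5 - base_icp) / h, 0.05), 0.95))
      ramp <- h * plogis((t - (on_s - d)) / tau) * plogis(((off_s + d) - t) / tau)
      icp <- icp + ramp
    }

    # compensatory-reserve state: pulse amplitude tracks the slow shared
    # drift (not the patient-specific waves), keeping RAP comparable across
    # groups, and rises during planted episodes
    amp <- 1.6 + 0.24 * s_shared + 0.06 * (base_icp - 9) + ar1_noise(n, 0.18) +
      0.1 * ramp

    clipped <- sum(icp < 0) + sum(map < 0) + sum(amp < 0)
    if (clipped > 0) warn(sprintf("%d negative pressure samples clipped to 0", clipped))
    tibble(
      time_s = t,
      icp = pmax(icp, 0),
      map = pmax(map, 0),
      amp = pmax(amp, 0)
    )
  })
}

#' Draw cohort ground truth and baseline covariates
#'
#' Draws outcome flags at the configured prevalences, planted episode onsets
#' and durations, and baseline covariates with the published group shifts
#' (event-positive patients older and with lower admission GCS; sex balanced
#' across groups at 66.7% male). Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return Tibble with one row per patient: `patient_id`, `age`, `sex`
#'   (0 = female, 1 = male), `gcs`, `is_ih`, `is_sih`, `group`,
#'   `onset_hours`, `duration_min`.
#' @export
sim_ground_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  if (n < 2) abort("`n_patients` must be >= 2")
  withr::with_seed(config$seed, {
    is_ih <- rbinom(n, 1, config$prevalence_ih) == 1
    is_sih <- is_ih & rbinom(n, 1, config$prevalence_sih_given_ih) == 1
    onset <- ifelse(is_ih, runif(n, config$ih_onset_hours_range[1],
                                 config$ih_onset_hours_range[2]), NA_real_)
    dur <- rep(NA_real_, n)
    dur[is_ih & !is_sih] <- runif(sum(is_ih & !is_sih),
                                  config$ih_duration_min_range[1],
                                  config$ih_duration_min_range[2])
    dur[is_sih] <- runif(sum(is_sih),
                         config$sih_duration_min_range[1],
                         config$sih_duration_min_range[2])
    sev <- as.numeric(is_ih) + as.numeric(is_sih)
    tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = pmin(pmax(round(rnorm(n, 50, 11) + 3.5 * sev), 18), 95),
      sex = rbinom(n, 1, 2 / 3),
      gcs = pmin(pmax(round(rnorm(n, 9.3, 2.4) - 1.3 * sev), 3), 15),
      is_ih = is_ih,
      is_sih = is_sih,
      group = severity_group(is_ih, is_sih),
      onset_hours = onset,
      duration_min = dur
    )
  })
}

#' Simulate a cohort of patient recordings
#'
#' Draws the ground truth via [sim_ground_truth()] and generates one raw
#' recording per patient via [sim_patient()]. Per-patient random substreams
#' are derived by hashing the patient id, so the cohort does not depend on
#' generation order.
#'
#' @param config A [sim_config()] object.
#' @return The [sim_ground_truth()] tibble with a `recording` list-column
#'   added.
#' @export
sim_cohort <- function(config = sim_config()) {
  gt <- sim_ground_truth(config)
  gt$recording <- map(seq_len(nrow(gt)), function(i) {
    sim_patient(config, gt$patient_id[i], gt[i, ])
  })
  gt
}
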