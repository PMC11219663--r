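#' Resample a raw recording to epoch averages
#'
#' Averages each uniformly sampled pressure channel over consecutive
#' non-overlapping epochs (12 s by default), the standard preprocessing step
#' that suppresses pulse and respiratory waves so that only slow ICP dynamics
#' remain. Samples recorded as `NA` count as missing; an epoch with more than
#' 50% missing samples is flagged invalid and its channel values are set to
#' `NA`. A trailing partial epoch is dropped.
#'
#' @param rec A recording data frame with columns `time_s`, `icp`, `map`, `amp`
#'   (mmHg), uniformly sampled (as produced by [sim_patient()] or
#'   [read_recording_csv()]).
#' @param epoch_s Epoch length in seconds; must be a positive multiple of the
#'   recording's sample period.
#' @return A tibble with one row per epoch: `epoch_idx`, `t_mid_s` (epoch
#'   midpoint in seconds from recording start), `icp`, `map`, `cpp`
#'   (`map - icp`), `amp`, and logical `valid`.
#' @examples
#' rec <- tibble::tibble(time_s = 0:23, icp = 1:24, map = 90, amp = 1)
#' resample_epochs(rec)$icp # 6.5, 18.5
#' @export
resample_epochs <- function(rec, epoch_s = 12) {
  stopifnot(is.data.frame(rec), all(c("time_s", "icp", "map", "amp") %in% names(rec)))
  if (nrow(rec) < 2) abort("recording too short to resample")
  period <- median(diff(rec$time_s))
  if (!is_number(epoch_s) || epoch_s <= 0) abort("`epoch_s` must be a positive number")
  k <- epoch_s / period
  if (abs(k - round(k)) > 1e-9) {
    abort(sprintf("`epoch_s` (%g s) is not a multiple of the sample period (%g s)", epoch_s, period))
  }
  k <- as.integer(round(k))
  n_epochs <- nrow(rec) %/% k
  if (n_epochs < 1) abort("recording shorter than one epoch")
  idx <- rep(seq_len(n_epochs), each = k)
  used <- seq_len(n_epochs * k)

  epoch_mean <- function(x) {
    m <- tapply(x[used], idx, function(v) mean(v, na.rm = TRUE))
    as.numeric(m)
  }
  miss <- as.numeric(tapply(is.na(rec$icp[used]) | is.na(rec$map[used]) | is.na(rec$amp[used]),
                            idx, mean))
  out <- tibble(
    epoch_idx = seq_len(n_epochs),
    t_mid_s = rec$time_s[1] + (seq_len(n_epochs) - 0.5) * epoch_s,
    icp = epoch_mean(rec$icp),
    map = epoch_mean(rec$map),
    amp = epoch_mean(rec$amp),
    valid = miss <= 0.5
  )
  out$icp[!out$valid] <- NA_real_
  out$map[!out$valid] <- NA_real_
  out$amp[!out$valid] <- NA_real_
  out$icp[is.nan(out$icp)] <- NA_real_
  out$map[is.nan(out$map)] <- NA_real_
  out$amp[is.nan(out$amp)] <- NA_real_
  out$valid <- out$valid & !is.na(out$icp) & !is.na(out$map) & !is.na(out$amp)
  out$cpp <- out$map - out$icp
  attr(out, "epoch_s") <- epoch_s
  out[, c("epoch_idx", "t_mid_s", "icp", "map", "cpp", "amp", "valid")]
}

#' Trailing moving-average smoother
#'
#' Span-`span` moving average with a causal (trailing) window: position `i` is
#' the mean of the last `min(span, i)` values. The shortened leading edge keeps
#' the output the same length as the input, and the causal orientation
#' guarantees no future samples leak into a feature window. `NA` (invalid)
#' entries propagate into every window that contains them.
#'
#' @param x Numeric vector.
#' @param span Window length in samples (default 4, i.e. 48 s on 12-s epochs).
#' @return Numeric vector, same length as `x`.
#' @examples
#' smooth_moving_average(c(1, 2, 3, 4, 5), span = 4) # 1 1.5 2 2.5 3.5
#' @export
smooth_moving_average <- function(x, span = 4) {
  if (!is_count(span)) abort("`span` must be a positive integer")
  n <- length(x)
  if (n == 0) abort("`x` must have length >= 1")
  if (span == 1) return(as.numeric(x))
  out <- as.numeric(stats::filter(x, rep(1 / span, span), sides = 1))
  for (i in seq_len(min(span - 1, n))) out[i] <- mean(x[seq_len(i)])
  out
}

#' Smooth the pressure channels of an epoch series
#'
#' Applies [smooth_moving_average()] to the ICP, MAP and AMP channels and
#' re-derives CPP as smoothed MAP minus smoothed ICP, preserving the
#' `cpp = map - icp` identity.
#'
#' @param es Epoch series from [resample_epochs()].
#' @inheritParams smooth_moving_average
#' @return An epoch series tibble of the same shape.
#' @export
smooth_epochs <- function(es, span = 4) {
  stopifnot(is.data.frame(es), all(c("icp", "map", "amp", "valid") %in% names(es)))
  es$icp <- smooth_moving_average(es$icp, span)
  es$map <- smooth_moving_average(es$map, span)
  es$amp <- smooth_moving_average(es$amp, span)
  es$cpp <- es$map - es$icp
  es$valid <- es$valid & !is.na(es$icp) & !is.na(es$map) & !is.na(es$amp)
  es
}

#' Extract a time window from an epoch series
#'
#' Keeps epochs whose midpoints fall in `[start_h, end_h)` hours from the
#' start of the recording, re-zeroing the time axis to the window start.
#'
#' @param es Epoch series tibble.
#' @param start_h,end_h Window bounds in hours, `0 <= start_h < end_h`.
#' @return The windowed epoch series; `epoch_idx` renumbered from 1 and
#'   `t_mid_s` measured from `start_h`. The original offset is kept in the
#'   `t0_offset_s` attribute.
#' @export
extract_window <- function(es, start_h, end_h) {
  stopifnot(is.data.frame(es))
  if (!is_number(start_h) || !is_number(end_h) || start_h < 0 || start_h >= end_h) {
    abort("need 0 <= start_h < end_h")
  }
  keep <- es$t_mid_s >= start_h * 3600 & es$t_mid_s < end_h * 3600
  if (!any(keep)) abort("window contains no epochs")
  out <- es[keep, , drop = FALSE]
  out$t_mid_s <- out$t_mid_s - start_h * 3600
  out$epoch_idx <- seq_len(nrow(out))
  attr(out, "epoch_s") <- attr(es, "epoch_s")
  attr(out, "t0_offset_s") <- start_h * 3600
  out
}

#' Pulse amplitude from a pulse-resolved ICP waveform
#'
#' Extracts the cardiac-cycle peak-to-trough excursion (AMP) of a fast-sampled
#' ICP signal: the waveform is band-passed to the cardiac band (0.66-3 Hz,
#' 4th-order Butterworth applied forward-backward) and the max-minus-min of
#' the filtered signal is taken over consecutive 10-s windows.
#'
#' @param pulse_icp Numeric ICP waveform sampled at `sample_rate_hz`.
#' @param sample_rate_hz Sampling rate; must be at least 20 Hz to resolve the
#'   pulse wave.
#' @return Nonnegative numeric vector, one value per complete 10-s window.
#' @export
extract_amp_from_pulse <- function(pulse_icp, sample_rate_hz) {
  if (!is_number(sample_rate_hz) || sample_rate_hz < 20) {
    abort("`sample_rate_hz` must be >= 20 Hz (pulse unresolvable below)")
  }
  if (length(pulse_icp) < 60 * sample_rate_hz) abort("segment must be at least 60 s long")
  bf <- signal::butter(4, c(0.66, 3) / (sample_rate_hz / 2), type = "pass")
  filt <- signal::filtfilt(bf, pulse_icp - mean(pulse_icp))
  w <- as.integer(round(10 * sample_rate_hz))
  n_win <- length(filt) %/% w
  vapply(seq_len(n_win), function(i) {
    seg <- filt[((i - 1) * w + 1):(i * w)]
    max(seg) - min(seg)
  }, numeric(1))
}
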