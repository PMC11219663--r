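#' Moving Pearson correlation
#'
#' Windowed Pearson correlation between two epoch-level series, the primitive
#' behind the pressure reactivity index (PRx) and the compensatory reserve
#' index (RAP). The value at position `i` is the correlation over the trailing
#' window of `window_epochs` epochs ending at `i`. A window yields `NA` when it
#' is incomplete (the first `window_epochs - 1` positions), contains any
#' invalid (`NA`) epoch, or has zero variance in either channel.
#'
#' @param x,y Numeric vectors of equal length; `NA` marks invalid epochs.
#' @param window_epochs Window length in epochs (>= 3; default 30, i.e. 6 min
#'   of 12-s epochs).
#' @return Numeric vector of correlations in `[-1, 1]` (or `NA`), same length
#'   as the inputs.
#' @examples
#' moving_pearson(c(1, 2, 3), c(2, 4, 6), 3) # NA NA 1
#' @export
moving_pearson <- function(x, y, window_epochs = 30) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (!is_count(window_epochs, min = 3)) abort("`window_epochs` must be an integer >= 3")
  n <- length(x)
  out <- rep(NA_real_, n)
  if (window_epochs > n) {
    warn("window longer than series; all values invalid")
    return(out)
  }
  ok <- !is.na(x) & !is.na(y)
  for (i in window_epochs:n) {
    w <- (i - window_epochs + 1):i
    if (!all(ok[w])) next
    xw <- x[w]
    yw <- y[w]
    if (sd(xw) == 0 || sd(yw) == 0) next
    out[i] <- min(1, max(-1, cor(xw, yw)))
  }
  out
}

#' Pressure reactivity index (PRx)
#'
#' Moving Pearson correlation between epoch-averaged ICP and MAP, a proxy for
#' cerebrovascular pressure reactivity: positive values indicate pressure-
#' passive (impaired) autoregulation.
#'
#' @param es Epoch series with `icp` and `map` columns (see
#'   [resample_epochs()]).
#' @inheritParams moving_pearson
#' @return Tibble `epoch_idx`, `value` with class attribute name `"PRx"`.
#' @export
prx <- function(es, window_epochs = 30) {
  stopifnot(is.data.frame(es), all(c("icp", "map") %in% names(es)))
  index_series("PRx", moving_pearson(es$icp, es$map, window_epochs), window_epochs)
}

#' Compensatory reserve index (RAP)
#'
#' Moving Pearson correlation between ICP pulse amplitude (AMP) and mean ICP.
#' Values near 0 indicate good cerebrospinal compensatory reserve (amplitude
#' insensitive to mean ICP); values near 1 indicate a working point on the
#' steep part of the pressure-volume curve.
#'
#' @param es Epoch series with `amp` and `icp` columns.
#' @inheritParams moving_pearson
#' @return Tibble `epoch_idx`, `value` with class attribute name `"RAP"`.
#' @export
rap <- function(es, window_epochs = 30) {
  stopifnot(is.data.frame(es), all(c("amp", "icp") %in% names(es)))
  index_series("RAP", moving_pearson(es$amp, es$icp, window_epochs), window_epochs)
}

index_series <- function(name, values, window_epochs) {
  out <- tibble(epoch_idx = seq_along(values), value = values)
  attr(out, "index_name") <- name
  attr(out, "window_epochs") <- window_epochs
  out
}

#' Mean over the valid values of a series
#'
#' The 6-h window summaries used as model features (`icp_m`, `cpp_m`, `prx_m`,
#' `rap_m`) are plain arithmetic means over the valid (non-`NA`) entries.
#'
#' @param xs Numeric vector (or an index tibble from [prx()]/[rap()]).
#' @return Scalar mean, or `NA` if no valid values (missing-feature marker).
#' @export
window_mean <- function(xs) {
  if (is.data.frame(xs)) xs <- xs$value
  v <- xs[!is.na(xs)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}
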