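#' Parameters for the nonlinear complexity features
#'
#' @param m Embedding dimension for sample entropy (default 2).
#' @param r_frac Match tolerance as a fraction of the series standard
#'   deviation (default 0.2).
#' @param lzc_binarize Binarization rule for Lempel-Ziv complexity: `"median"`
#'   (default, balanced symbol frequencies) or `"mean"`.
#' @param lzc_normalized Report normalized Lempel-Ziv complexity
#'   `c(n) * log2(n) / n` (default) rather than the raw phrase count.
#' @return A list of class `complexity_params`.
#' @export
complexity_params <- function(m = 2, r_frac = 0.2, lzc_binarize = c("median", "mean"),
                              lzc_normalized = TRUE) {
  if (!is_count(m)) abort("`m` must be a positive integer")
  if (!is_number(r_frac) || r_frac <= 0) abort("`r_frac` must be > 0")
  lzc_binarize <- match.arg(lzc_binarize)
  if (!is_flag(lzc_normalized)) abort("`lzc_normalized` must be TRUE or FALSE")
  structure(list(m = m, r_frac = r_frac, lzc_binarize = lzc_binarize,
                 lzc_normalized = lzc_normalized),
            class = "complexity_params")
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B), where B counts ordered template pairs of length
#' `m` (and A of length `m + 1`) whose Chebyshev (max-norm) distance is at
#' most `r = r_frac * sd(x)`; self-matches are excluded and both counts use
#' templates starting at positions `1 .. N - m`. Low values mean a regular,
#' predictable series; white noise scores high. Because `r` scales with the
#' series SD, SampEn is invariant to affine rescaling.
#'
#' A constant series returns 0 by convention; if no (m+1)-length matches exist
#' the conditional probability is 0 and `Inf` is returned.
#'
#' @param x Numeric series with at least `m + 2` finite values.
#' @param params A [complexity_params()] object (uses `m` and `r_frac`).
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
sample_entropy <- function(x, params = complexity_params()) {
  x <- as.numeric(x[!is.na(x)])
  m <- params$m
  n <- length(x)
  if (n < m + 2) abort("series too short for sample entropy")
  if (!all(is.finite(x))) abort("series must be finite")
  s <- sd(x)
  if (s == 0) return(0)
  r <- params$r_frac * s

  # max-norm template distance matrices built incrementally over lags
  d <- abs(outer(x, x, "-"))
  nt <- n - m # templates of length m and m+1 both start at 1..n-m
  dm <- d[1:nt, 1:nt, drop = FALSE]
  if (m > 1) {
    for (k in 1:(m - 1)) dm <- pmax(dm, d[1:nt + k, 1:nt + k, drop = FALSE])
  }
  dm1 <- pmax(dm, d[1:nt + m, 1:nt + m, drop = FALSE])
  b <- sum(dm <= r) - nt   # subtract self-matches on the diagonal
  a <- sum(dm1 <= r) - nt
  if (b == 0) return(Inf)  # unreachable for n >= m+2 with r > 0, kept defensively
  if (a == 0) return(Inf)
  -log(a / b)
}

#' Binarize a numeric series
#'
#' Maps the series to a 0/1 symbol string for Lempel-Ziv analysis: symbol 1
#' where the value exceeds the threshold (sample median by default, mean as
#' alternative), else 0.
#'
#' @param x Numeric series with at least 2 valid values.
#' @param rule `"median"` (default) or `"mean"`.
#' @return Character scalar of 0/1 symbols, one per valid value.
#' @examples
#' binarize(c(1, 2, 3, 4)) # "0011"
#' @export
binarize <- function(x, rule = c("median", "mean")) {
  rule <- match.arg(rule)
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("need at least 2 valid values to binarize")
  if (length(unique(x)) == 1) {
    warn("all values equal; binarized string is all zeros")
    return(paste(rep("0", length(x)), collapse = ""))
  }
  thr <- if (rule == "median") median(x) else mean(x)
  paste(ifelse(x > thr, "1", "0"), collapse = "")
}

#' Lempel-Ziv complexity (LZ76 exhaustive parsing)
#'
#' Parses a binary symbol string into the minimal number of phrases under the
#' exhaustive production rule: the current phrase ends at the first symbol
#' that makes it impossible to copy the phrase from anywhere in the preceding
#' string (the copy source may overlap the phrase itself); a trailing
#' still-reproducible phrase counts as one. The phrase count `c(n)` measures
#' the rate at which new patterns appear; the normalized form
#' `c(n) * log2(n) / n` approaches 1 for long equiprobable random strings and
#' 0 for strongly redundant ones.
#'
#' @param s Binary string (character scalar of `"0"`/`"1"`), length >= 2.
#' @param normalized Return the normalized complexity (default `TRUE`).
#' @return Nonnegative scalar.
#' @examples
#' lempel_ziv("000000000000", normalized = FALSE) # 2
#' @export
lempel_ziv <- function(s, normalized = TRUE) {
  stopifnot(is.character(s), length(s) == 1)
  n <- nchar(s)
  if (n < 2) abort("string must have length >= 2")
  if (grepl("[^01]", s)) abort("string must contain only 0 and 1")
  cn <- 0L
  u <- 1L
  while (u <= n) {
    v <- u
    # grow the phrase while s[u..v] can be copied from within s[1..v-1]
    repeat {
      if (v > n) break # trailing reproducible phrase
      if (u == 1L && v == 1L) break # very first symbol is always new
      if (!grepl(substr(s, u, v), substr(s, 1L, v - 1L), fixed = TRUE)) break
      v <- v + 1L
    }
    cn <- cn + 1L
    u <- v + 1L
  }
  if (normalized) cn * log2(n) / n else as.numeric(cn)
}

#' Nonlinear complexity features of a 6-h epoch window
#'
#' Computes the four nonlinear features used by the prediction models: sample
#' entropy and Lempel-Ziv complexity of the ICP and CPP epoch series. Invalid
#' epochs are dropped (the series is concatenated across gaps) before
#' analysis.
#'
#' @param es6h Epoch series restricted to the feature window (see
#'   [extract_window()]).
#' @param params A [complexity_params()] object.
#' @param min_valid Minimum number of valid epochs required (default 100);
#'   below it all four features are returned as `NA`.
#' @return One-row tibble `icp_sampen`, `cpp_sampen`, `icp_lzc`, `cpp_lzc`.
#' @export
complexity_features <- function(es6h, params = complexity_params(), min_valid = 100) {
  stopifnot(is.data.frame(es6h), all(c("icp", "cpp", "valid") %in% names(es6h)))
  icp <- es6h$icp[es6h$valid]
  cpp <- es6h$cpp[es6h$valid]
  if (length(icp) < min_valid) {
    return(tibble(icp_sampen = NA_real_, cpp_sampen = NA_real_,
                  icp_lzc = NA_real_, cpp_lzc = NA_real_))
  }
  lz <- function(x) {
    s <- suppressWarnings(binarize(x, params$lzc_binarize))
    lempel_ziv(s, normalized = params$lzc_normalized)
  }
  tibble(
    icp_sampen = sample_entropy(icp, params),
    cpp_sampen = sample_entropy(cpp, params),
    icp_lzc = lz(icp),
    cpp_lzc = lz(cpp)
  )
}
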