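# Independent reference implementations used to verify the package's
# algorithms. These deliberately use different algorithms / code paths than
# the implementations they check.

# brute-force sample entropy by explicit O(N^2) template counting
oracle_sampen <- function(x, m, r_frac = 0.2) {
  n <- length(x)
  s <- sd(x)
  if (s == 0) return(0)
  r <- r_frac * s
  count_pairs <- function(len) {
    nt <- n - m # both template lengths use starts 1 .. n - m
    total <- 0L
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r) {
          total <- total + 1L
        }
      }
    }
    total
  }
  b <- count_pairs(m)
  a <- count_pairs(m + 1)
  if (a == 0 || b == 0) return(Inf)
  -log(a / b)
}

# LZ76 exhaustive-parsing complexity, Kaspar-Schuster pointer formulation
# (no substring search; independent of the package's implementation)
oracle_lz76 <- function(s) {
  v <- as.integer(strsplit(s, "")[[1]])
  n <- length(v)
  cn <- 1L
  l <- 1L
  i <- 0L
  k <- 1L
  k_max <- 1L
  repeat {
    if (v[i + k] == v[l + k]) {
      k <- k + 1L
      if (l + k > n) {
        cn <- cn + 1L
        break
      }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        cn <- cn + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L
        k <- 1L
        k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  cn
}

# textbook Pearson correlation from the definitional sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# AUC as the Mann-Whitney pair count with ties scored 1/2
oracle_auc_pairs <- function(scores, labels) {
  labels <- as.logical(labels)
  sp <- scores[labels]
  sn <- scores[!labels]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

# exhaustive Youden scan over all candidate cutoffs
oracle_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  cands <- c(-Inf, sort(unique(scores)), Inf)
  j <- vapply(cands, function(cut) {
    sens <- mean(scores[labels] > cut)
    spec <- mean(scores[!labels] <= cut)
    sens + spec - 1
  }, numeric(1))
  best <- which(j == max(j))
  list(cutoff = min(cands[best]), j = max(j))
}

# flat synthetic recording with given channel values at 1 Hz
flat_recording <- function(hours, icp = 10, map = 90, amp = 1.5) {
  n <- hours * 3600
  tibble::tibble(time_s = seq_len(n) - 1, icp = rep_len(icp, n),
                 map = rep_len(map, n), amp = rep_len(amp, n))
}

# epoch series built directly from an epoch-level ICP vector (12-s epochs)
epochs_from_icp <- function(icp, epoch_s = 12) {
  es <- tibble::tibble(
    epoch_idx = seq_along(icp),
    t_mid_s = (seq_along(icp) - 0.5) * epoch_s,
    icp = icp, map = rep(90, length(icp)), cpp = 90 - icp,
    amp = rep(1.5, length(icp)), valid = !is.na(icp)
  )
  attr(es, "epoch_s") <- epoch_s
  es
}

# random binary string of length n
random_bits <- function(n) paste(sample(c("0", "1"), n, replace = TRUE), collapse = "")

# synthetic feature table with `n_signal` informative and `n_noise` pure-noise
# features; informative features are shifted by `effect` SDs in positives
planted_feature_table <- function(n, n_signal = 3, n_noise = 7, effect = 0.9,
                                  prevalence = 0.5) {
  y <- rbinom(n, 1, prevalence) == 1
  cols <- list()
  for (i in seq_len(n_signal)) cols[[paste0("sig", i)]] <- rnorm(n) + effect * y
  for (i in seq_len(n_noise)) cols[[paste0("noise", i)]] <- rnorm(n)
  out <- tibble::as_tibble(cols)
  out$ih <- y
  out
}
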