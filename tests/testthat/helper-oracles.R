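# Independent brute-force oracles: explicit loops, no shared code with the
# package internals.

# artifact labelling by the published rule: nearest-k neighbour median,
# ties at equal distance broken toward the earlier index
oracle_flag <- function(x, k = 5, thr = 0.30) {
  n <- length(x)
  out <- character(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- order(abs(others - i), others)
    nb <- others[ord][seq_len(min(k, n - 1))]
    med <- median(x[nb])
    out[i] <- if (abs(x[i] - med) / med > thr) "abnormal" else "normal"
  }
  out
}

# nightly RMSSD by explicit loops, given per-IBI labels
oracle_night_rmssd <- function(t, ibi, labels, seg_min = 5,
                               min_valid_fraction = 0.5,
                               min_normal_ibis = 30) {
  seg_len <- seg_min * 60
  n_seg <- floor(max(t) / seg_len) + 1
  seg_rmssd <- numeric(0)
  for (k in 0:(n_seg - 1)) {
    sel <- which(t >= k * seg_len & t < (k + 1) * seg_len)
    n_tot <- length(sel)
    norm <- sel[labels[sel] == "normal"]
    frac <- if (n_tot > 0) length(norm) / n_tot else 0
    if (frac >= min_valid_fraction && length(norm) >= max(min_normal_ibis, 2)) {
      xs <- ibi[norm]
      ss <- 0
      for (j in 2:length(xs)) ss <- ss + (xs[j] - xs[j - 1])^2
      seg_rmssd <- c(seg_rmssd, sqrt(ss / (length(xs) - 1)))
    }
  }
  if (!length(seg_rmssd)) return(NA_real_)
  mean(seg_rmssd)
}

# prior-days rolling SD by explicit window enumeration
oracle_rolling_sd <- function(dates, values, window_days = 7, min_obs = 3) {
  out <- rep(NA_real_, length(dates))
  for (i in seq_along(dates)) {
    w <- numeric(0)
    for (lag in 1:window_days) {
      j <- which(dates == dates[i] - lag)
      if (length(j) == 1 && !is.na(values[j])) w <- c(w, values[j])
    }
    if (length(w) >= min_obs) out[i] <- sd(w)
  }
  out
}

# closed-form OLS slope
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# normal-equations OLS coefficients by explicit linear solve
oracle_lm_coefs <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# random synthetic IBI night (mean interval, RMSSD-like jitter, a few
# spikes), returning timestamps and intervals
random_ibi_night <- function(duration_min, mean_ibi = 1000, sd_ibi = 40,
                             spike_rate = 0.01) {
  n <- ceiling(duration_min * 60 * 1000 / mean_ibi) + 5
  ibi <- rnorm(n, mean_ibi, sd_ibi)
  ibi <- pmax(ibi, 300)
  sp <- runif(n) < spike_rate
  ibi[sp] <- ibi[sp] * 1.9
  t <- cumsum(c(0, ibi[-n])) / 1000
  keep <- t < duration_min * 60
  list(t = t[keep], ibi = ibi[keep])
}

# complete random 4DSQ response vector
random_4dsq_items <- function() {
  sample(c("no", "sometimes", "regularly", "often", "very_often"), 50,
         replace = TRUE, prob = c(0.5, 0.25, 0.1, 0.1, 0.05))
}
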