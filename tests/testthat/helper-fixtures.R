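# Shared fixtures: small simulator configs and closed-form filter responses.

quick_cfg <- function(n_infants = 2, duration_s = 900, n_channels = 3,
                      seed = 11, n_pauses = 3, dur_range_s = c(6, 30),
                      min_gap_s = 100, ...) {
  sim_config(n_infants = n_infants, duration_s = duration_s,
             n_channels = n_channels, seed = seed,
             pause_spec = list(n = n_pauses, dur_range_s = dur_range_s,
                               min_gap_s = min_gap_s), ...)
}

tone <- function(f, fs, dur, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * (seq_len(round(dur * fs)) - 1) / fs + phase)
}

# Squared magnitude (forward-backward application) of an analog order-2
# Butterworth high-pass at frequency f for cut-off fc.
butter2_hp_gain2 <- function(f, fc) {
  r <- (f / fc)^4
  r / (1 + r)
}

# Same for the order-2-prototype band-pass between lo and hi.
butter2_bp_gain2 <- function(f, lo, hi) {
  w <- 2 * pi * f; wl <- 2 * pi * lo; wh <- 2 * pi * hi
  x <- (w^2 - wl * wh) / (w * (wh - wl))
  1 / (1 + x^4)
}

# Data with exactly zero between-infant variation: every infant shares the
# same covariate and residual pattern, so the REML variance estimates
# collapse to zero and the mixed-model slope must equal OLS.
zero_ranef_data <- function(n_infants = 20, n_per_infant = 12,
                            beta0 = 0.1, beta1 = 0.002, resid_sd = 0.04,
                            seed = 1) {
  set.seed(seed)
  x_pat <- rnorm(n_per_infant)
  r_pat <- rnorm(n_per_infant, 0, resid_sd)
  data.frame(eeg_change = rep(beta0 + beta1 * x_pat + r_pat, n_infants),
             x = rep(x_pat, n_infants),
             infant_id = rep(sprintf("i%03d", seq_len(n_infants)),
                             each = n_per_infant))
}

# Independent brute-force Benjamini-Hochberg step-up.
bh_bruteforce <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(n) / n)
  mask <- logical(n)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  mask
}

# Independent O(n^2) isolation oracle.
isolation_oracle <- function(events, all_pauses, before_s = 60, after_s = 90) {
  sapply(seq_len(nrow(events)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(all_pauses))) {
      if (abs(all_pauses$start_s[j] - events$start_s[i]) < 1e-9 &&
            abs(all_pauses$end_s[j] - events$end_s[i]) < 1e-9) next
      lo <- events$start_s[i] - before_s
      hi <- events$end_s[i] + after_s
      if ((all_pauses$start_s[j] >= lo && all_pauses$start_s[j] <= hi) ||
            (all_pauses$end_s[j] >= lo && all_pauses$end_s[j] <= hi))
        hit <- TRUE
    }
    !hit
  })
}

breath_series_from_times <- function(times) {
  structure(list(breath_times = times, ibis = diff(times), fs = NA),
            class = "breath_series")
}
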