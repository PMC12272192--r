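# Synthetic multimodal recordings with known ground truth.
#
# Every modality draws from its own derived RNG stream so that generating a
# subset of modalities never changes the values of another (and a fixed seed
# makes the whole recording byte-identical).

EEG_CHANNELS <- c("Fp1", "Fp2", "C3", "Cz", "C4", "T3", "T4", "O1", "O2")
SLEEP_STATES <- c("TA", "HVS", "ASI", "LVI")

# 1/f-amplitude ("pink") noise by spectral shaping: flat below f0, amplitude
# ~ 1/sqrt(f) above, i.e. power-spectral slope ~ 1 over the band of interest.
pink_noise <- function(n, fs, f0 = 0.5) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, f0))
  g[1] <- 0                                 # no DC
  x <- Re(stats::fft(X * g, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Times at which the noiseless carrier sin(phase) crosses `level` upward.
carrier_crossings <- function(phase, fs, level = 0.35) {
  c0 <- sin(phase)
  up <- which(c0[-length(c0)] < level & c0[-1] >= level)
  (up - 1 + (level - c0[up]) / (c0[up + 1] - c0[up])) / fs
}

draw_pause_intervals <- function(cfg) {
  if (cfg$pause_explicit) {
    m <- do.call(rbind, lapply(cfg$pause_spec, function(p) c(p[1], p[2])))
    return(m[order(m[, 1]), , drop = FALSE])
  }
  ps <- cfg$pause_spec
  n <- ps$n
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  dur <- exp(stats::runif(n, log(ps$dur_range_s[1]), log(ps$dur_range_s[2])))
  # one pause per equal-width slot keeps the requested minimum gap
  margin <- 150
  slot <- (cfg$duration_s - 2 * margin) / n
  if (slot < max(dur) + ps$min_gap_s)
    stop("recording too short for requested pause count / gap")
  onset <- margin + (seq_len(n) - 1) * slot +
    stats::runif(n, 0, pmax(0, slot - dur - ps$min_gap_s))
  cbind(onset, dur)
}

#' Simulate one infant's multimodal recording
#'
#' Generates a thoracic (and abdominal) respiration trace with breathing
#' pauses, multichannel 1/f-background EEG whose instantaneous amplitude is
#' multiplied by \code{10^suppression_log10} during each pause (persisting
#' \code{post_end_hold_s} seconds past the pause end), heart-rate and SpO2
#' series with lagged severity-coupled dips, and a 30-s-epoch sleep-state
#' label sequence. Pause onsets and offsets are snapped to breath-cycle times
#' of the carrier so the ground-truth interval endpoints coincide with the
#' last breath before and the first breath after the cessation.
#'
#' @param config a [sim_config()].
#' @param infant infant index in \code{1:config$n_infants}.
#' @param modalities character subset of
#'   \code{c("resp", "eeg", "vitals", "sleep")} to generate.
#' @return a list with elements \code{recording} (class
#'   \code{"apneeg_recording"}: signals, sampling rates, ids, PMA) and
#'   \code{truth} (class \code{"apneeg_truth"}: the injected pause intervals
#'   with per-event severity and suppression, the infant's random coupling
#'   slope, and the sleep labels).
#' @export
simulate_recording <- function(config, infant = 1,
                               modalities = c("resp", "eeg", "vitals", "sleep")) {
  stopifnot(inherits(config, "sim_config"),
            infant >= 1, infant <= config$n_infants)
  modalities <- match.arg(modalities, several.ok = TRUE)
  base <- derive_seed(config$seed, infant)
  dur <- config$duration_s

  # infant-level traits
  set.seed(derive_seed(base, 0))
  pma <- min(48, max(31, stats::rnorm(1, 38.6, 2.7)))
  hr_base <- stats::runif(1, 120, 170)
  f0 <- config$breath_rate_hz * (1 + 0.1 * stats::rnorm(1))
  slope_dev <- stats::rnorm(1, 0, config$infant_slope_sd)
  pauses <- draw_pause_intervals(config)

  # breathing carrier phase (shared by resp generation and pause snapping)
  nr <- round(dur * config$fs_resp)
  freq_mod <- 1 + 0.05 * stats::filter(stats::rnorm(nr), rep(1 / 200, 200),
                                       sides = 1)
  freq_mod[is.na(freq_mod)] <- 1
  phase <- cumsum(2 * pi * f0 * as.numeric(freq_mod) / config$fs_resp)
  bt <- carrier_crossings(phase, config$fs_resp)

  # snap each requested pause to breath-cycle endpoints
  intervals <- matrix(numeric(0), ncol = 2)
  if (nrow(pauses) > 0) {
    snap <- t(apply(pauses, 1, function(p) {
      a <- bt[bt <= p[1]]
      b <- bt[bt >= p[1] + p[2]]
      if (length(a) == 0 || length(b) == 0) return(c(NA, NA))
      c(max(a), min(b))
    }))
    snap <- snap[stats::complete.cases(snap), , drop = FALSE]
    if (nrow(snap) > 1 && any(snap[-1, 1] <= snap[-nrow(snap), 2]))
      stop("pauses overlap after snapping; increase min_gap_s")
    intervals <- snap
  }
  dur_ev <- intervals[, 2] - intervals[, 1]
  severity <- dur_ev
  supp_ev <- if (config$suppression_mode == "severity") {
    config$suppression_log10 * dur_ev / 20
  } else rep(config$suppression_log10, length(dur_ev))

  rec <- list(infant_id = sprintf("inf%03d", infant),
              recording_id = sprintf("rec%03d", infant),
              pma_weeks = pma, fs_resp = config$fs_resp,
              fs_eeg = config$fs_eeg, fs_vitals = config$fs_vitals,
              duration_s = dur)

  in_interval <- function(t, a, b) t >= a & t < b

  if ("resp" %in% modalities) {
    set.seed(derive_seed(base, 1))
    tr <- (seq_len(nr) - 1) / config$fs_resp
    env <- rep(1, nr)
    for (i in seq_len(nrow(intervals)))
      env[in_interval(tr, intervals[i, 1] + 0.15, intervals[i, 2] - 0.15)] <-
        config$residual_frac
    thorax <- env * sin(phase) +
      stats::rnorm(nr, 0, config$noise_levels$resp)
    abdomen <- 0.8 * env * sin(phase + 0.2) +
      stats::rnorm(nr, 0, config$noise_levels$resp * 1.5)
    rec$resp <- list(thorax = thorax, abdomen = abdomen)
  }

  if ("eeg" %in% modalities) {
    set.seed(derive_seed(base, 2))
    ne <- round(dur * config$fs_eeg)
    te <- (seq_len(ne) - 1) / config$fs_eeg
    mod <- rep(1, ne)
    for (i in seq_len(nrow(intervals))) {
      a <- intervals[i, 1]; b <- intervals[i, 2] + config$post_end_hold_s
      mod[in_interval(te, a, b)] <- 10^supp_ev[i]
      if (config$ramp_on && config$ramp_s > 0) {
        ridx <- which(in_interval(te, a - config$ramp_s, a))
        mod[ridx] <- 10^(supp_ev[i] * (te[ridx] - (a - config$ramp_s)) /
                           config$ramp_s)
      }
    }
    eeg <- matrix(0, ne, config$n_channels,
                  dimnames = list(NULL, EEG_CHANNELS[seq_len(config$n_channels)]))
    for (ch in seq_len(config$n_channels))
      eeg[, ch] <- pink_noise(ne, config$fs_eeg) * config$eeg_rms_uv * mod
    rec$eeg <- eeg
  }

  if ("vitals" %in% modalities) {
    set.seed(derive_seed(base, 3))
    nv <- round(dur * config$fs_vitals)
    tv <- (seq_len(nv) - 1) / config$fs_vitals
    wander <- stats::filter(stats::rnorm(nv, 0, 0.4), rep(1 / 60, 60),
                            sides = 1)
    wander[is.na(wander)] <- 0
    hr <- hr_base + 5 * as.numeric(wander) +
      stats::rnorm(nv, 0, config$noise_levels$hr)
    spo2 <- 97 + stats::rnorm(nv, 0, config$noise_levels$spo2)
    for (i in seq_len(nrow(intervals))) {
      end_i <- intervals[i, 2]
      hr <- hr - (config$hr_coupling + slope_dev) * severity[i] *
        exp(-(tv - (end_i + config$hr_lag_s))^2 / (2 * 8^2))
      spo2 <- spo2 - config$spo2_coupling * severity[i] *
        exp(-(tv - (end_i + config$spo2_lag_s))^2 / (2 * 15^2))
    }
    hr <- pmin(pmax(hr, 45), 225)
    spo2 <- pmin(pmax(spo2, 60), 100)    # monitor floor at 60%
    rec$vitals <- data.frame(time_s = tv, hr_bpm = hr, spo2_pct = spo2)
  }

  sleep <- NULL
  if ("sleep" %in% modalities) {
    set.seed(derive_seed(base, 4))
    n_ep <- ceiling(dur / 30)
    lab <- character(n_ep)
    lab[1] <- sample(SLEEP_STATES, 1)
    for (i in seq_len(n_ep - 1))
      lab[i + 1] <- if (stats::runif(1) < 0.85) lab[i] else
        sample(setdiff(SLEEP_STATES, lab[i]), 1)
    sleep <- data.frame(epoch_start_s = (seq_len(n_ep) - 1) * 30,
                        state = lab)
    rec$sleep <- sleep
  }

  truth <- list(intervals = data.frame(
                  start_s = intervals[, 1], end_s = intervals[, 2],
                  duration_s = dur_ev, severity = severity,
                  suppression_log10 = supp_ev),
                infant_slope = slope_dev,
                hr_baseline_bpm = hr_base,
                pma_weeks = pma,
                sleep = sleep)
  class(rec) <- "apneeg_recording"
  class(truth) <- "apneeg_truth"
  list(recording = rec, truth = truth)
}

#' @export
print.apneeg_recording <- function(x, ...) {
  cat(sprintf("Recording %s (infant %s, PMA %.1f wk): %.0f s\n",
              x$recording_id, x$infant_id, x$pma_weeks, x$duration_s))
  mods <- intersect(c("resp", "eeg", "vitals", "sleep"), names(x))
  cat("  modalities:", paste(mods, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.apneeg_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d pause(s), infant coupling deviation %.3f\n",
              nrow(x$intervals), x$infant_slope))
  if (nrow(x$intervals)) print(utils::head(x$intervals, 10))
  invisible(x)
}

#' Simulate a cohort of recordings
#'
#' @param config a [sim_config()].
#' @param modalities passed to [simulate_recording()].
#' @return list of length \code{config$n_infants}; each element as returned
#'   by [simulate_recording()].
#' @export
simulate_cohort <- function(config,
                            modalities = c("resp", "eeg", "vitals", "sleep")) {
  lapply(seq_len(config$n_infants), function(i)
    simulate_recording(config, i, modalities))
}

#' Generate labelled breathing-pause candidates for classifier training
#'
#' Emits a balanced mixture of true cessations (respiration envelope collapses
#' to the residual fraction) and false candidates (shallow breathing: the
#' envelope drops only to 20-40% of baseline), each as a short thoracic
#' segment from which the six classifier features are extracted. Candidates
#' are distributed across the configured infants, with infant-specific
#' amplitude scaling, so leave-one-infant-out folds are meaningful.
#'
#' @param config a [sim_config()].
#' @param n_true,n_false candidates per class (each >= 2).
#' @param shallow_range envelope fraction range for false candidates.
#' @return data frame: six feature columns (\code{pre_meanabs, pre_sd,
#'   post_meanabs, post_sd, in_meanabs, in_sd}), \code{label} (factor
#'   false/true), \code{infant_id}, \code{duration_s}.
#' @export
make_labelled_candidates <- function(config, n_true = 100, n_false = 100,
                                     shallow_range = c(0.2, 0.4)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_true < 2 || n_false < 2)
    stop("need at least 2 candidates per class")
  set.seed(derive_seed(config$seed, 555))
  n <- n_true + n_false
  lab <- rep(c("true", "false"), c(n_true, n_false))
  infant <- rep_len(seq_len(config$n_infants), n)
  amp <- stats::runif(config$n_infants, 0.5, 2)   # per-infant gain
  fs <- config$fs_resp
  seg_dur <- 60
  nt <- round(seg_dur * fs)
  t <- (seq_len(nt) - 1) / fs
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- stats::runif(1, 5, 15)
    a <- 25; b <- a + d
    frac <- if (lab[i] == "true") config$residual_frac else
      stats::runif(1, shallow_range[1], shallow_range[2])
    env <- ifelse(t >= a & t < b, frac, 1)
    f <- config$breath_rate_hz * (1 + 0.1 * stats::rnorm(1))
    x <- amp[infant[i]] *
      (env * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi)) +
         stats::rnorm(nt, 0, config$noise_levels$resp))
    ev <- data.frame(start_s = a, end_s = b, duration_s = d)
    fe <- extract_features(x, fs, ev, recording_sd = stats::sd(x))
    fe$label <- lab[i]
    fe$infant_id <- sprintf("inf%03d", infant[i])
    fe$duration_s <- d
    rows[[i]] <- fe
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = c("false", "true"))
  rownames(out) <- NULL
  out
}
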