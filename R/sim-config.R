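#' Configuration for the synthetic multimodal physiology generator
#'
#' Bundles and validates every knob of the simulator: cohort size, recording
#' duration, per-modality sampling rates, breathing dynamics, breathing-pause
#' placement, the injected EEG amplitude suppression, vitals coupling, and
#' noise levels. The defaults describe a plausible neonatal intensive-care
#' recording: quasi-periodic breathing near 0.75 Hz, pauses of 5-40 s placed
#' far enough apart to be isolated, 1/f-like EEG at around 30 uV RMS on nine
#' channels, heart rate baselines of 120-170 bpm and SpO2 near 97% with
#' monitor-style floors.
#'
#' @param n_infants number of infants (one recording each).
#' @param duration_s recording duration in seconds (>= 300).
#' @param fs_eeg,fs_resp,fs_vitals sampling rates in Hz.
#' @param breath_rate_hz mean breathing frequency in Hz.
#' @param pause_spec either a list of \code{c(onset_s, duration_s)} pairs for
#'   explicit placement, or a list with elements \code{n} (pauses per
#'   recording), \code{dur_range_s} (durations drawn log-uniformly within) and
#'   \code{min_gap_s} (minimum separation between pauses).
#' @param suppression_log10 injected EEG amplitude change during pauses, in
#'   log10 units (negative = suppression).
#' @param suppression_mode \code{"constant"}: every event gets
#'   \code{suppression_log10}; \code{"severity"}: the injected change scales
#'   linearly with pause duration (normalised so a 20-s pause gets the nominal
#'   value).
#' @param post_end_hold_s seconds the EEG suppression persists after breathing
#'   resumes (cortical recovery lags the breath; default 5 s).
#' @param ramp_on,ramp_s optional linear pre-onset suppression ramp; off by
#'   default so that null simulations are clean.
#' @param residual_frac residual respiration envelope inside a pause
#'   (chest-wall stillness; default 2%).
#' @param hr_coupling bradycardia depth in bpm per second of pause duration.
#' @param spo2_coupling desaturation depth in percentage points per second of
#'   pause duration.
#' @param infant_slope_sd between-infant SD of the heart-rate coupling
#'   (random slope in the coupling between event severity and the dip).
#' @param hr_lag_s,spo2_lag_s delay of the heart-rate / SpO2 nadir after the
#'   pause end, in seconds.
#' @param n_channels number of EEG channels (up to 9, 10-20 subset
#'   referenced to Cz).
#' @param eeg_rms_uv EEG background RMS in microvolts.
#' @param noise_levels list of additive noise SDs: \code{resp} (fraction of
#'   breath amplitude), \code{hr} (bpm), \code{spo2} (percentage points).
#' @param seed integer RNG seed; a fixed seed makes the whole cohort
#'   byte-identical across runs.
#' @return an object of class \code{"sim_config"}.
#' @seealso [simulate_recording()], [make_labelled_candidates()]
#' @export
sim_config <- function(n_infants = 20,
                       duration_s = 1800,
                       fs_eeg = 250,
                       fs_resp = 25,
                       fs_vitals = 1,
                       breath_rate_hz = 0.75,
                       pause_spec = list(n = 8, dur_range_s = c(6, 40),
                                         min_gap_s = 180),
                       suppression_log10 = -0.2,
                       suppression_mode = c("constant", "severity"),
                       post_end_hold_s = 5,
                       ramp_on = FALSE,
                       ramp_s = 5,
                       residual_frac = 0.02,
                       hr_coupling = 1.0,
                       spo2_coupling = 0.4,
                       infant_slope_sd = 0.2,
                       hr_lag_s = 10,
                       spo2_lag_s = 25,
                       n_channels = 9,
                       eeg_rms_uv = 30,
                       noise_levels = list(resp = 0.05, hr = 1.5, spo2 = 0.4),
                       seed = 1L) {
  suppression_mode <- match.arg(suppression_mode)
  stopifnot(n_infants >= 1, duration_s >= 300,
            fs_eeg > 0, fs_resp > 0, fs_vitals > 0,
            breath_rate_hz > 0, residual_frac >= 0, residual_frac < 1,
            post_end_hold_s >= 0, ramp_s >= 0,
            n_channels >= 1, n_channels <= 9, eeg_rms_uv > 0)
  if (!is.list(pause_spec)) stop("pause_spec must be a list")
  explicit <- is.null(pause_spec$n)
  if (explicit) {
    iv <- do.call(rbind, lapply(pause_spec, function(p) c(p[1], p[1] + p[2])))
    if (any(iv[, 2] > duration_s))
      stop("requested pause extends beyond the recording")
    if (nrow(iv) > 1) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop("requested pauses overlap")
    }
  } else {
    stopifnot(pause_spec$n >= 0, length(pause_spec$dur_range_s) == 2,
              all(pause_spec$dur_range_s > 0),
              pause_spec$dur_range_s[2] < duration_s)
    pause_spec$min_gap_s <- pause_spec$min_gap_s %||% 180
  }
  cfg <- list(n_infants = as.integer(n_infants), duration_s = duration_s,
              fs_eeg = fs_eeg, fs_resp = fs_resp, fs_vitals = fs_vitals,
              breath_rate_hz = breath_rate_hz, pause_spec = pause_spec,
              pause_explicit = explicit,
              suppression_log10 = suppression_log10,
              suppression_mode = suppression_mode,
              post_end_hold_s = post_end_hold_s,
              ramp_on = ramp_on, ramp_s = ramp_s,
              residual_frac = residual_frac,
              hr_coupling = hr_coupling, spo2_coupling = spo2_coupling,
              infant_slope_sd = infant_slope_sd,
              hr_lag_s = hr_lag_s, spo2_lag_s = spo2_lag_s,
              n_channels = as.integer(n_channels), eeg_rms_uv = eeg_rms_uv,
              noise_levels = noise_levels, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic physiology configuration\n")
  cat(sprintf("  %d infant(s), %.0f s each; resp %.0f Hz, EEG %.0f Hz (%d ch), vitals %.0f Hz\n",
              x$n_infants, x$duration_s, x$fs_resp, x$fs_eeg, x$n_channels,
              x$fs_vitals))
  if (x$pause_explicit) {
    cat(sprintf("  pauses: %d explicit\n", length(x$pause_spec)))
  } else {
    cat(sprintf("  pauses: %d per recording, %.0f-%.0f s, gap >= %.0f s\n",
                x$pause_spec$n, x$pause_spec$dur_range_s[1],
                x$pause_spec$dur_range_s[2], x$pause_spec$min_gap_s))
  }
  cat(sprintf("  EEG suppression %.3f log10 (%s), held %.0f s past pause end\n",
              x$suppression_log10, x$suppression_mode, x$post_end_hold_s))
  cat(sprintf("  couplings: HR %.2f bpm/s (infant SD %.2f), SpO2 %.2f %%/s; seed %d\n",
              x$hr_coupling, x$infant_slope_sd, x$spo2_coupling, x$seed))
  invisible(x)
}
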