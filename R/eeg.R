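# EEG band-pass, epoching, amplitude-based artifact screening, and the
# narrowband Hilbert time-frequency amplitude (TFA) transform.

TFA_CF <- seq(1.5, 29.5, by = 1)   # centre frequencies, Hz

#' Band-pass filter EEG
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass,
#' 0.1-30 Hz by default, applied per channel. Infant EEG carries little
#' power above 30 Hz, so the spectral analysis is restricted below the gamma
#' band.
#'
#' @param eeg numeric vector or samples-by-channels matrix, in microvolts.
#' @param fs sampling rate in Hz (>= 100).
#' @param band length-2 numeric, Hz.
#' @return filtered signal, same shape as \code{eeg}.
#' @export
bandpass_eeg <- function(eeg, fs, band = c(0.1, 30)) {
  stopifnot(fs >= 100)
  if (any(!is.finite(eeg))) stop("bandpass_eeg: non-finite input")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  pad <- round(5 / band[1] * fs)   # settling time of the low cut-off
  if (is.matrix(eeg)) {
    out <- eeg
    for (ch in seq_len(ncol(eeg))) out[, ch] <- filtfilt_pad(bf, eeg[, ch], pad)
    out
  } else {
    filtfilt_pad(bf, eeg, pad)
  }
}

#' Cut event-locked EEG epochs
#'
#' Extracts fixed-length segments around each event's lock point (pause start
#' or end). Events whose window would cross a recording edge are dropped and
#' reported.
#'
#' @param eeg samples-by-channels matrix.
#' @param fs sampling rate in Hz.
#' @param events data frame with \code{start_s}, \code{end_s}.
#' @param lock \code{"start"} or \code{"end"}.
#' @param window length-2 numeric, seconds relative to the lock point (e.g.
#'   \code{c(-90, 150)} for apnoeas, \code{c(-90, 90)} for short pauses).
#' @return list with \code{epochs} (list of matrices, each with a
#'   \code{time_s} attribute relative to the lock point), \code{kept}
#'   (indices into \code{events}) and \code{dropped}.
#' @export
epoch_eeg <- function(eeg, fs, events, lock = c("start", "end"),
                      window = c(-90, 150)) {
  lock <- match.arg(lock)
  if (!is.matrix(eeg)) eeg <- matrix(eeg, ncol = 1)
  n <- nrow(eeg)
  lock_t <- if (lock == "start") events$start_s else events$end_s
  epochs <- list(); kept <- integer(0); dropped <- integer(0)
  for (i in seq_along(lock_t)) {
    idx <- time_window_idx(lock_t[i] + window[1], lock_t[i] + window[2], fs, n)
    need <- round((window[2] - window[1]) * fs)
    if (length(idx) < need) {
      dropped <- c(dropped, i)
      next
    }
    ep <- eeg[idx, , drop = FALSE]
    attr(ep, "time_s") <- (idx - 1) / fs - lock_t[i]
    epochs[[length(epochs) + 1]] <- ep
    kept <- c(kept, i)
  }
  if (length(dropped))
    message(length(dropped), " event(s) dropped: epoch crosses recording edge")
  list(epochs = epochs, kept = kept, dropped = dropped)
}

#' Amplitude-based channel-wise epoch rejection
#'
#' A channel of an epoch is rejected when any sample lies outside
#' \code{c(-limit_uv, limit_uv)} microvolts; other channels of the same epoch
#' are kept.
#'
#' @param epochs list of samples-by-channels matrices (microvolts).
#' @param limit_uv rejection limit (default 500).
#' @return logical keep-matrix, epochs by channels.
#' @export
reject_epochs <- function(epochs, limit_uv = 500) {
  if (length(epochs) == 0) return(matrix(logical(0), nrow = 0, ncol = 0))
  nch <- ncol(epochs[[1]])
  keep <- matrix(TRUE, length(epochs), nch)
  for (i in seq_along(epochs))
    keep[i, ] <- apply(abs(epochs[[i]]) <= limit_uv, 2, all)
  colnames(keep) <- colnames(epochs[[1]])
  keep
}

#' Time-frequency amplitude via iterative narrowband Hilbert envelopes
#'
#' For each centre frequency f in 1.5, 2.5, ..., 29.5 Hz, band-pass filters
#' the epoch between f-1 and f+1 Hz (zero-phase second-order Butterworth),
#' takes the modulus of the analytic signal as the instantaneous amplitude,
#' and log10-transforms it (with a small floor so silent signals stay
#' finite). Filter and Hilbert edge effects contaminate roughly the first and
#' last 2 s; downstream statistics discard those edges.
#'
#' @param epoch samples-by-channels matrix, already broadband-filtered.
#' @param fs sampling rate in Hz.
#' @param cfs centre frequencies in Hz.
#' @param half_bw half-bandwidth in Hz (band = cf +/- half_bw).
#' @param floor_uv amplitude floor in microvolts before the log.
#' @return array time x frequency x channel of log10 amplitudes, with
#'   attributes \code{cfs}, \code{fs} and (if present on the epoch)
#'   \code{time_s}.
#' @export
tfa <- function(epoch, fs, cfs = TFA_CF, half_bw = 1, floor_uv = 1e-6) {
  if (!is.matrix(epoch)) epoch <- matrix(epoch, ncol = 1)
  if (nrow(epoch) < 10 * fs)
    stop("tfa: epoch shorter than 10 s; edge effects dominate")
  out <- array(NA_real_, c(nrow(epoch), length(cfs), ncol(epoch)),
               dimnames = list(NULL, NULL, colnames(epoch)))
  for (k in seq_along(cfs)) {
    bf <- signal::butter(2, c(cfs[k] - half_bw, cfs[k] + half_bw) / (fs / 2),
                         type = "pass")
    for (ch in seq_len(ncol(epoch))) {
      env <- Mod(analytic_signal(signal::filtfilt(bf, epoch[, ch])))
      out[, k, ch] <- log10(pmax(env, floor_uv))
    }
  }
  attr(out, "cfs") <- cfs
  attr(out, "fs") <- fs
  if (!is.null(attr(epoch, "time_s"))) attr(out, "time_s") <- attr(epoch, "time_s")
  out
}

# TFA of the sub-window [a, b) of a recording-long signal, computed on a
# padded cut so the window interior is free of filter edge effects. Always
# returns exactly round((b - a) * fs) / decim time samples so segments from
# different events stack into one array; `out_fs` (divisor of fs) decimates
# the stored envelope, which varies far more slowly than the carrier.
# Time axis is relative to `rel_to`.
tfa_segment <- function(eeg, fs, a, b, pad_s = 5, rel_to = a, out_fs = fs,
                        ...) {
  if (!is.matrix(eeg)) eeg <- matrix(eeg, ncol = 1)
  n <- nrow(eeg)
  decim <- fs / out_fs
  if (abs(decim - round(decim)) > 1e-9)
    stop("tfa_segment: out_fs must divide fs")
  decim <- as.integer(round(decim))
  i0 <- floor(a * fs + 1e-9) + 1L
  need <- as.integer(round((b - a) * fs))
  p <- as.integer(round(pad_s * fs))
  lo <- i0 - p; hi <- i0 + need - 1L + p
  if (lo < 1L || hi > n) return(NULL)
  arr <- tfa(eeg[lo:hi, , drop = FALSE], fs, ...)
  rows <- seq.int(p + 1L, p + need, by = decim)
  out <- arr[rows, , , drop = FALSE]
  attr(out, "cfs") <- attr(arr, "cfs")
  attr(out, "fs") <- out_fs
  attr(out, "time_s") <- (seq.int(i0, i0 + need - 1L, by = decim) - 1) / fs -
    rel_to
  out
}

#' Event-minus-baseline change map
#'
#' Subtracts the normal-breathing baseline's log10 amplitude from the event's,
#' sample-wise: the baseline window's samples are mapped one-to-one onto the
#' event segment's time axis (the two must have identical shape). Set
#' \code{baseline_average = TRUE} to instead subtract the baseline's
#' time-averaged spectrum from every time sample.
#'
#' @param event_tfa,baseline_tfa arrays from [tfa()] of identical shape.
#' @param baseline_average collapse the baseline over time first?
#' @return difference array (log10 units), event attributes preserved.
#' @export
change_map <- function(event_tfa, baseline_tfa, baseline_average = FALSE) {
  if (baseline_average) {
    bl <- apply(baseline_tfa, c(2, 3), mean)
    out <- sweep(event_tfa, c(2, 3), bl, "-")
  } else {
    if (!identical(dim(event_tfa), dim(baseline_tfa)))
      stop("change_map: shape mismatch between event and baseline")
    out <- event_tfa - baseline_tfa
  }
  attributes(out)[c("cfs", "fs", "time_s")] <-
    attributes(event_tfa)[c("cfs", "fs", "time_s")]
  out
}
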