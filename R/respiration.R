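# Respiration preprocessing, adaptive breath detection, pause extraction,
# the isolation filter, and baseline-window selection.

#' Preprocess a respiration trace
#'
#' High-pass filters the trace with a zero-phase (forward-backward)
#' second-order Butterworth filter at 0.5 Hz, then removes amplitude
#' outliers: samples exceeding 5 times the signal's standard deviation are
#' replaced by linear interpolation between their neighbours, iterated 10
#' times. The same outlier rule is also applied once in the raw domain
#' before filtering: a zero-phase filter smears an impulsive artifact over
#' its settling time, beyond what post-hoc interpolation can repair, so
#' gross spikes are excised while they are still single samples.
#'
#' @param x numeric respiration trace.
#' @param fs sampling rate in Hz (> 1).
#' @param hp_hz high-pass cut-off in Hz.
#' @param outlier_k outlier threshold in SD units.
#' @param n_iter outlier-removal iterations.
#' @return cleaned numeric trace, same length as \code{x}.
#' @export
preprocess_respiration <- function(x, fs, hp_hz = 0.5, outlier_k = 5,
                                   n_iter = 10) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("preprocess_respiration: input must be finite numeric")
  stopifnot(fs > 1)
  deglitch <- function(y, iters) {
    for (iter in seq_len(iters)) {
      centred <- y - stats::median(y)
      bad <- abs(centred) > outlier_k * stats::sd(centred)
      if (!any(bad)) break
      if (all(bad))
        stop("preprocess_respiration: all samples flagged as outliers")
      good <- which(!bad)
      y[bad] <- stats::approx(good, y[good], xout = which(bad), rule = 2)$y
    }
    y
  }
  x <- deglitch(x, n_iter)
  bf <- signal::butter(2, hp_hz / (fs / 2), type = "high")
  y <- filtfilt_pad(bf, x, round(5 / hp_hz * fs))
  deglitch(y, n_iter)
}

#' Detect breaths with an adaptive amplitude threshold
#'
#' A breath is an upward crossing of a positive threshold equal to \code{k}
#' times the standard deviation of the signal spanning the previous \code{w}
#' detected breaths. Before \code{w} breaths exist, the SD is taken over all
#' breaths so far, seeded by the SD of the first \code{warmup_s} seconds.
#' Crossings closer than \code{refractory_s} to the previous breath are
#' merged. Because the threshold scales with the signal's SD, detection is
#' invariant to overall amplitude scaling.
#'
#' @param x preprocessed respiration trace.
#' @param fs sampling rate in Hz.
#' @param k threshold factor (default 0.5; the originally published
#'   impedance-pneumography algorithm used 0.4).
#' @param w number of previous breaths spanned by the SD window (default 120;
#'   originally 15).
#' @param refractory_s minimum breath separation in seconds.
#' @param warmup_s seconds used to seed the threshold.
#' @return object of class \code{"breath_series"}: list with
#'   \code{breath_times} (s, strictly increasing), \code{ibis} (s) and
#'   \code{fs}.
#' @export
detect_breaths <- function(x, fs, k = 0.5, w = 120, refractory_s = 0.5,
                           warmup_s = 60) {
  n <- length(x)
  if (n < 10 * fs) stop("detect_breaths: trace too short")
  thr <- k * stats::sd(x[seq_len(min(n, round(warmup_s * fs)))])
  breaths <- numeric(0)        # interpolated crossing times (s)
  breath_idx <- integer(0)     # sample index just after each crossing
  i <- 2L
  chunk <- 8192L
  while (i <= n) {
    j2 <- min(n, i + chunk)
    seg_prev <- x[(i - 1L):(j2 - 1L)]
    seg_cur <- x[i:j2]
    hits <- which(seg_prev < thr & seg_cur >= thr)
    advanced <- FALSE
    for (h in hits) {
      ii <- i + h - 1L           # crossing between ii-1 and ii
      tt <- (ii - 2 + (thr - x[ii - 1L]) / (x[ii] - x[ii - 1L])) / fs
      if (length(breaths) && tt - breaths[length(breaths)] < refractory_s)
        next
      breaths <- c(breaths, tt)
      breath_idx <- c(breath_idx, ii)
      nb <- length(breaths)
      if (nb >= 2) {
        first <- breath_idx[max(1L, nb - w + 1L)]
        thr <- k * stats::sd(x[first:ii])
      }
      i <- ii + 1L
      advanced <- TRUE
      break                      # re-scan with the updated threshold
    }
    if (!advanced) i <- j2 + 1L
  }
  structure(list(breath_times = breaths,
                 ibis = diff(breaths),
                 fs = fs),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("Breath series: %d breaths", length(x$breath_times)))
  if (length(x$ibis))
    cat(sprintf(", median IBI %.2f s (max %.2f s)",
                stats::median(x$ibis), max(x$ibis)))
  cat("\n")
  invisible(x)
}

#' Extract breathing pauses from a breath series
#'
#' Every inter-breath interval with duration in \code{[min_s, max_s)} becomes
#' a pause event, categorised as an apnoea (>= 15 s) or a short breathing
#' pause (5-15 s).
#'
#' @param breaths a \code{"breath_series"}.
#' @param min_s,max_s duration bounds in seconds (closed-open).
#' @return data frame of class \code{"pause_events"}: \code{start_s} (last
#'   breath before the cessation), \code{end_s} (next breath),
#'   \code{duration_s}, \code{category}.
#' @export
find_pauses <- function(breaths, min_s = 5, max_s = Inf) {
  stopifnot(inherits(breaths, "breath_series"))
  bt <- breaths$breath_times
  ibi <- breaths$ibis
  sel <- which(ibi >= min_s & ibi < max_s)
  out <- data.frame(start_s = bt[sel], end_s = bt[sel + 1],
                    duration_s = ibi[sel])
  out$category <- ifelse(out$duration_s >= 15, "apnoea",
                         ifelse(out$duration_s >= 5, "short", "sub"))
  class(out) <- c("pause_events", "data.frame")
  out
}

#' Flag isolated pauses
#'
#' A pause is isolated if no other pause of at least 5 s starts or ends
#' inside the window from 60 s before its start to 90 s after its end.
#' Isolation restricts the analysis to single events, excluding periodic
#' breathing and clustered pauses.
#'
#' @param events pause events to flag (data frame with \code{start_s},
#'   \code{end_s}).
#' @param all_pauses all pauses of >= 5 s from the same recording (usually a
#'   superset of \code{events}).
#' @param before_s,after_s window extent in seconds.
#' @return \code{events} with a logical \code{isolated} column.
#' @export
filter_isolated <- function(events, all_pauses, before_s = 60, after_s = 90) {
  iso <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    lo <- events$start_s[i] - before_s
    hi <- events$end_s[i] + after_s
    self <- abs(all_pauses$start_s - events$start_s[i]) < 1e-9 &
      abs(all_pauses$end_s - events$end_s[i]) < 1e-9
    other <- all_pauses[!self, , drop = FALSE]
    iso[i] <- !any((other$start_s >= lo & other$start_s <= hi) |
                     (other$end_s >= lo & other$end_s <= hi))
  }
  events$isolated <- iso
  events
}

#' Select the normal-breathing baseline window for an event
#'
#' Scans candidate windows of length \code{win_s} on a 1-s grid inside the
#' 90 s preceding the pause start (ending at least
#' \code{search_end_offset_s} before it) and returns the window whose maximal
#' overlapping inter-breath interval is lowest, i.e. the stretch with the
#' most regular breathing. Ties go to the earliest window.
#'
#' @param breaths a \code{"breath_series"}.
#' @param event one pause event (list/row with \code{start_s}).
#' @param win_s window length: 30 s for apnoeas, 10 s for short pauses.
#' @param search_end_offset_s gap between window end and pause start: 15 s
#'   for apnoeas, 5 s for short pauses.
#' @param search_back_s how far back the search extends (default 90 s).
#' @return \code{c(start_s, end_s)} of the selected window, or \code{NULL} if
#'   there is insufficient pre-event data (such events are excluded
#'   downstream).
#' @export
select_baseline_window <- function(breaths, event, win_s = 30,
                                   search_end_offset_s = 15,
                                   search_back_s = 90) {
  stopifnot(inherits(breaths, "breath_series"))
  t0 <- event$start_s
  a0 <- t0 - search_back_s
  a_max <- t0 - search_end_offset_s - win_s
  if (a0 < 0 || a_max < a0) return(NULL)
  starts <- seq(a0, a_max, by = 1)
  bt <- breaths$breath_times
  ibi <- breaths$ibis
  worst <- vapply(starts, function(a) {
    b <- a + win_s
    ov <- bt[-length(bt)] < b & bt[-1] > a
    if (!any(ov)) return(Inf)
    max(ibi[ov])
  }, numeric(1))
  if (!any(is.finite(worst))) return(NULL)
  a <- starts[which.min(worst)]      # which.min takes the earliest tie
  c(a, a + win_s)
}
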