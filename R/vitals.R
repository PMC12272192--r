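# Heart-rate and SpO2 cleaning and per-event change computation.

#' Clean heart-rate and SpO2 series
#'
#' Marks physiologically impossible samples as missing rather than
#' interpolating them: heart rate below 40 or above 230 bpm, SpO2 above
#' 100%. SpO2 values equal to 60% are kept but flagged as possibly
#' truncated, since bedside monitors floor the reading there.
#'
#' @param hr heart-rate series, bpm.
#' @param spo2 SpO2 series, percent.
#' @return list with \code{hr}, \code{spo2} (NAs where invalid) and logical
#'   \code{spo2_floor} (sample touched the 60% floor).
#' @export
clean_vitals <- function(hr, spo2) {
  hr_c <- ifelse(!is.finite(hr) | hr < 40 | hr > 230, NA_real_, hr)
  spo2_c <- ifelse(!is.finite(spo2) | spo2 > 100, NA_real_, spo2)
  list(hr = hr_c, spo2 = spo2_c,
       spo2_floor = !is.na(spo2_c) & spo2_c == 60)
}

#' Per-event vitals change
#'
#' The change is the minimum of the series in the window from 5 s before to
#' 60 s after the pause end, minus the mean over the event's normal-breathing
#' baseline window. Missing samples are excluded from both statistics; the
#' event is invalid when either window has less than \code{min_coverage}
#' non-missing data.
#'
#' @param values cleaned series (from [clean_vitals()]).
#' @param time_s sample times in seconds.
#' @param end_s pause end time in seconds.
#' @param baseline_window \code{c(start_s, end_s)} from
#'   [select_baseline_window()].
#' @param window event window relative to \code{end_s}, seconds.
#' @param min_coverage minimum non-missing fraction per window.
#' @return list with \code{change}, \code{valid}, \code{event_min},
#'   \code{baseline_mean}.
#' @export
event_change <- function(values, time_s, end_s, baseline_window,
                         window = c(-5, 60), min_coverage = 0.5) {
  ev <- values[time_s >= end_s + window[1] & time_s < end_s + window[2]]
  bl <- values[time_s >= baseline_window[1] & time_s < baseline_window[2]]
  ok <- length(ev) > 0 && length(bl) > 0 &&
    mean(!is.na(ev)) >= min_coverage && mean(!is.na(bl)) >= min_coverage
  if (!ok)
    return(list(change = NA_real_, valid = FALSE,
                event_min = NA_real_, baseline_mean = NA_real_))
  m <- min(ev, na.rm = TRUE)
  b <- mean(bl, na.rm = TRUE)
  list(change = m - b, valid = TRUE, event_min = m, baseline_mean = b)
}
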