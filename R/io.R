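# Plain-text I/O: tidy CSV signals, ground truth, and config echo.

#' Write a simulated recording to plain-text files
#'
#' Respiration and vitals go to tidy CSVs (\code{time_s,value} /
#' \code{time_s,hr_bpm,spo2_pct}), EEG to a wide CSV (one column per
#' channel), and sleep labels and ground-truth pause intervals to CSVs. The
#' generating configuration travels in the pipeline manifest instead (see
#' [run_pipeline()]).
#'
#' @param sim list from [simulate_recording()] (\code{recording} +
#'   \code{truth}).
#' @param dir output directory (created if missing).
#' @param write_eeg include the (large) EEG matrix?
#' @return \code{dir}, invisibly.
#' @export
write_recording <- function(sim, dir, write_eeg = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- sim$recording
  tr <- (seq_along(rec$resp$thorax) - 1) / rec$fs_resp
  utils::write.csv(data.frame(time_s = tr, value = rec$resp$thorax),
                   file.path(dir, "resp_thorax.csv"), row.names = FALSE)
  utils::write.csv(rec$vitals, file.path(dir, "vitals.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$sleep, file.path(dir, "sleep.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$intervals, file.path(dir, "truth_pauses.csv"),
                   row.names = FALSE)
  if (write_eeg && !is.null(rec$eeg)) {
    te <- (seq_len(nrow(rec$eeg)) - 1) / rec$fs_eeg
    utils::write.csv(cbind(data.frame(time_s = te), as.data.frame(rec$eeg)),
                     file.path(dir, "eeg.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a tidy signal CSV
#'
#' Reads a two-column \code{time_s,value} CSV as written by
#' [write_recording()].
#'
#' @param path file path.
#' @return data frame with \code{time_s} and \code{value}.
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(d)))
  d
}
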