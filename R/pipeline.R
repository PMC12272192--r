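# End-to-end orchestration: simulate -> detect -> classify -> TFA -> vitals
# -> group statistics, as one seeded, reproducible run.

# Event/baseline statistical segment extents (s) by category.
segment_half_width <- function(category) if (category == "apnoea") 15 else 5
baseline_length <- function(category) if (category == "apnoea") 30 else 10
baseline_offset <- function(category) if (category == "apnoea") 15 else 5
epoch_window <- function(category)
  if (category == "apnoea") c(-90, 150) else c(-90, 90)

fit_lm_simple <- function(d, covariate, response = "eeg_change") {
  fml <- stats::as.formula(paste(response, "~", covariate))
  m <- stats::lm(fml, data = d)
  ct <- stats::coef(summary(m))
  structure(list(beta0 = unname(ct[1, 1]), beta1 = unname(ct[-1, 1]),
                 se_beta1 = unname(ct[-1, 2]), p_beta1 = unname(ct[-1, 4])[1],
                 df_method = "OLS t", covariate = covariate,
                 categorical = FALSE,
                 random_structure = "none (one row per infant)",
                 varcor = NULL, random_effects = NULL,
                 residuals = stats::residuals(m),
                 n_events = nrow(d), n_infants = nrow(d), model = m),
            class = "pause_lmm")
}

# Stack a list of identically-shaped arrays along a new leading dimension,
# NA-ing out rejected channels.
stack_segments <- function(lst, keep) {
  d <- dim(lst[[1]])
  big <- array(NA_real_, c(length(lst), d))
  for (e in seq_along(lst)) {
    a <- lst[[e]]
    if (!is.null(keep)) a[, , !keep[e, ]] <- NA_real_
    big[e, , , ] <- a
  }
  attr(big, "time_s") <- attr(lst[[1]], "time_s")
  attr(big, "cfs") <- attr(lst[[1]], "cfs")
  big
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the configured cohort, then runs every stage: respiration
#' preprocessing and adaptive breath detection; pause extraction and
#' categorisation (apnoea >= 15 s, short pause 5-15 s); the isolation filter;
#' classifier training on generated labelled candidates and screening of the
#' detected events; per-event normal-breathing baseline selection; EEG
#' band-pass, epoching, amplitude-based channel rejection and narrowband
#' Hilbert time-frequency amplitudes; heart-rate and SpO2 changes; paired
#' t-maps with BH FDR control (channel-wise and channel-pooled, start- and
#' end-locked, per category); and the five random-slope mixed-effects models
#' (heart-rate change, SpO2 change, duration, post-menstrual age, sleep
#' state).
#'
#' The run is fully deterministic given \code{config$seed}.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, events, per-event changes,
#'   model results, t-map summaries and a run manifest are written as
#'   CSV/JSON.
#' @param q FDR level for the t-maps.
#' @param tfa_out_fs stored envelope sampling rate (Hz; must divide
#'   \code{fs_eeg}).
#' @param use_classifier screen detected events with the logistic classifier
#'   trained on [make_labelled_candidates()]?
#' @param summary_window time window (s, relative to pause end) over which
#'   the per-event scalar EEG change is averaged.
#' @return object of class \code{"apneeg_run"}: \code{events} (per-event
#'   table), \code{tmaps}, \code{lmm} (list of \code{"pause_lmm"}),
#'   \code{manifest}, \code{config}.
#' @export
run_pipeline <- function(config, out_dir = NULL, q = 0.01, tfa_out_fs = 10,
                         use_classifier = TRUE, summary_window = c(-5, 5)) {
  stopifnot(inherits(config, "sim_config"))

  clf <- NULL
  if (use_classifier) {
    cand <- make_labelled_candidates(config)
    clf <- train_classifier(cand)
  }

  rows <- list()
  seg_store <- list()   # per retained event: start/end-locked + baseline TFA
  counts <- c(breaths = 0, candidates = 0, apnoea = 0, short = 0,
              classified_true = 0, classified_false = 0,
              classified_excluded = 0, isolated = 0, baseline_ok = 0,
              epochs_retained = 0, channels_rejected = 0)

  for (inf in seq_len(config$n_infants)) {
    sim <- simulate_recording(config, inf)
    rec <- sim$recording
    thorax <- preprocess_respiration(rec$resp$thorax, rec$fs_resp)
    rec_sd <- stats::sd(thorax)
    breaths <- detect_breaths(thorax, rec$fs_resp)
    counts["breaths"] <- counts["breaths"] + length(breaths$breath_times)
    events <- find_pauses(breaths, 5, Inf)
    if (nrow(events) == 0) next
    events <- filter_isolated(events, events)
    counts["candidates"] <- counts["candidates"] + nrow(events)
    counts["apnoea"] <- counts["apnoea"] + sum(events$category == "apnoea")
    counts["short"] <- counts["short"] + sum(events$category == "short")
    counts["isolated"] <- counts["isolated"] + sum(events$isolated)

    vit <- clean_vitals(rec$vitals$hr_bpm, rec$vitals$spo2_pct)
    eeg_bp <- bandpass_eeg(rec$eeg, rec$fs_eeg)

    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      row <- data.frame(recording_id = rec$recording_id,
                        infant_id = rec$infant_id,
                        pma_weeks = rec$pma_weeks,
                        start_s = ev$start_s, end_s = ev$end_s,
                        duration_s = ev$duration_s, category = ev$category,
                        isolated = ev$isolated,
                        p_true = NA_real_, verdict = NA,
                        baseline_start_s = NA_real_, baseline_end_s = NA_real_,
                        hr_change = NA_real_, hr_valid = FALSE,
                        spo2_change = NA_real_, spo2_valid = FALSE,
                        spo2_floor_hit = FALSE,
                        sleep_state = NA_character_,
                        eeg_change = NA_real_, retained = FALSE)

      fe <- extract_features(thorax, rec$fs_resp, ev, rec_sd)
      if (is.null(fe) || anyNA(fe)) {
        counts["classified_excluded"] <- counts["classified_excluded"] + 1
        rows[[length(rows) + 1]] <- row
        next
      }
      if (use_classifier) {
        vd <- classify(clf, fe)
        row$p_true <- vd$p_true
        row$verdict <- vd$verdict
        if (isTRUE(vd$verdict)) {
          counts["classified_true"] <- counts["classified_true"] + 1
        } else {
          counts["classified_false"] <- counts["classified_false"] + 1
        }
      } else {
        row$verdict <- TRUE
        counts["classified_true"] <- counts["classified_true"] + 1
      }

      ep_idx <- floor(ev$start_s / 30) + 1
      if (!is.null(rec$sleep) && ep_idx <= nrow(rec$sleep))
        row$sleep_state <- rec$sleep$state[ep_idx]

      bl <- select_baseline_window(breaths, ev,
                                   win_s = baseline_length(ev$category),
                                   search_end_offset_s = baseline_offset(ev$category))
      if (!is.null(bl)) {
        row$baseline_start_s <- bl[1]; row$baseline_end_s <- bl[2]
        counts["baseline_ok"] <- counts["baseline_ok"] + 1

        hrc <- event_change(vit$hr, rec$vitals$time_s, ev$end_s, bl)
        row$hr_change <- hrc$change; row$hr_valid <- hrc$valid
        spc <- event_change(vit$spo2, rec$vitals$time_s, ev$end_s, bl)
        row$spo2_change <- spc$change; row$spo2_valid <- spc$valid
        evwin <- rec$vitals$time_s >= ev$end_s - 5 &
          rec$vitals$time_s < ev$end_s + 60
        row$spo2_floor_hit <- any(vit$spo2_floor[evwin])
      }

      eligible <- ev$isolated && !is.null(bl) &&
        (!use_classifier || isTRUE(row$verdict))
      if (eligible) {
        win <- epoch_window(ev$category)
        epo <- suppressMessages(
          epoch_eeg(rec$eeg, rec$fs_eeg, ev, lock = "start", window = win))
        if (length(epo$kept) == 1) {
          keep <- reject_epochs(epo$epochs, limit_uv = 500)[1, ]
          counts["channels_rejected"] <- counts["channels_rejected"] +
            sum(!keep)
          if (any(keep)) {
            hw <- segment_half_width(ev$category)
            seg_end <- tfa_segment(eeg_bp, rec$fs_eeg, ev$end_s - hw,
                                   ev$end_s + hw, rel_to = ev$end_s,
                                   out_fs = tfa_out_fs)
            seg_start <- tfa_segment(eeg_bp, rec$fs_eeg, ev$start_s - hw,
                                     ev$start_s + hw, rel_to = ev$start_s,
                                     out_fs = tfa_out_fs)
            seg_bl <- tfa_segment(eeg_bp, rec$fs_eeg, bl[1], bl[2],
                                  rel_to = bl[1], out_fs = tfa_out_fs)
            if (!is.null(seg_end) && !is.null(seg_start) &&
                  !is.null(seg_bl)) {
              cm <- change_map(seg_end, seg_bl)
              cm[, , !keep] <- NA_real_
              row$eeg_change <- summarize_change(cm, summary_window)
              row$retained <- TRUE
              counts["epochs_retained"] <- counts["epochs_retained"] + 1
              seg_store[[length(seg_store) + 1]] <-
                list(category = ev$category, keep = keep,
                     end = seg_end, start = seg_start, baseline = seg_bl)
            }
          }
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }

  events_df <- if (length(rows)) do.call(rbind, rows) else
    stop("run_pipeline: no candidate pauses detected")
  rownames(events_df) <- NULL

  # group-level t-maps per category and lock, channel-wise and pooled
  tmaps <- list()
  for (cat in c("apnoea", "short")) {
    idx <- which(vapply(seg_store, function(s) s$category == cat, logical(1)))
    if (length(idx) < 2) next
    keep <- do.call(rbind, lapply(seg_store[idx], function(s) s$keep))
    bl <- stack_segments(lapply(seg_store[idx], function(s) s$baseline), keep)
    for (lock in c("start", "end")) {
      evs <- stack_segments(lapply(seg_store[idx], function(s) s[[lock]]),
                            keep)
      tm <- ttest_map(evs, bl, q = q)
      tm$time_s <- attr(seg_store[[idx[1]]][[lock]], "time_s")
      pool <- function(a) {
        out <- apply(a, c(1, 2, 3), mean, na.rm = TRUE)
        out[is.nan(out)] <- NA_real_
        dim(out) <- c(dim(out), 1L)
        out
      }
      tmp <- ttest_map(pool(evs), pool(bl), q = q)
      tmp$time_s <- tm$time_s
      tmaps[[paste(cat, lock, sep = "_")]] <-
        list(channelwise = tm, pooled = tmp, n_events = length(idx))
    }
  }

  # five mixed-effects models on retained events
  ret <- events_df[events_df$retained & !is.na(events_df$eeg_change), ]
  lmm <- list()
  if (nrow(ret) >= 10 && length(unique(ret$infant_id)) >= 3) {
    try_fit <- function(d, cov) tryCatch(suppressWarnings(fit_lmm(d, cov)),
                                         error = function(e) NULL)
    lmm$hr_change <- try_fit(ret[ret$hr_valid, ], "hr_change")
    lmm$spo2_change <- try_fit(ret[ret$spo2_valid, ], "spo2_change")
    lmm$duration_s <- try_fit(ret, "duration_s")
    agg <- stats::aggregate(cbind(eeg_change, pma_weeks) ~ infant_id,
                            data = ret, FUN = mean)
    lmm$pma_weeks <- if (nrow(agg) >= 5)
      tryCatch(fit_lm_simple(agg, "pma_weeks"), error = function(e) NULL)
    sl <- ret[!is.na(ret$sleep_state), ]
    sl$sleep_state <- factor(sl$sleep_state, levels = SLEEP_STATES)
    if (nlevels(droplevels(sl$sleep_state)) >= 2) {
      sl$sleep_state <- droplevels(sl$sleep_state)
      lmm$sleep_state <- try_fit(sl, "sleep_state")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("apneeg")),
    seed = config$seed,
    n_infants = config$n_infants,
    counts = as.list(counts),
    parameters = list(resp_highpass_hz = 0.5, outlier_k = 5, outlier_iter = 10,
                      breath_threshold_k = 0.5, breath_window = 120,
                      pause_bounds_s = c(5, 15), isolation_s = c(-60, 90),
                      reject_limit_uv = 500, tfa_cf_hz = range(TFA_CF),
                      fdr_q = q, summary_window_s = summary_window,
                      tfa_out_fs = tfa_out_fs),
    config = unclass(config))

  res <- structure(list(events = events_df, tmaps = tmaps, lmm = lmm,
                        manifest = manifest, config = config,
                        classifier = clf),
                   class = "apneeg_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

lmm_results_table <- function(lmm) {
  do.call(rbind, lapply(names(lmm), function(nm) {
    m <- lmm[[nm]]
    if (is.null(m)) return(NULL)
    data.frame(model = nm, beta0 = m$beta0, beta1 = m$beta1[1],
               se = m$se_beta1[1], p = m$p_beta1,
               n_events = m$n_events, n_infants = m$n_infants,
               random_structure = m$random_structure,
               df_method = m$df_method)
  }))
}

tmap_summary_table <- function(tmaps) {
  do.call(rbind, lapply(names(tmaps), function(nm) {
    do.call(rbind, lapply(c("channelwise", "pooled"), function(scope) {
      tm <- tmaps[[nm]][[scope]]
      ok <- !is.na(tm$p)
      data.frame(comparison = nm, scope = scope,
                 n_events = tmaps[[nm]]$n_events,
                 n_samples = sum(ok),
                 frac_significant = mean(tm$significant[ok]),
                 mean_t = mean(tm$t[ok]))
    }))
  }))
}

#' Write pipeline outputs to a directory
#'
#' Emits \code{events.csv}, \code{lmm_results.csv}, \code{lmm_results.json},
#' \code{tmap_summary.csv} and \code{manifest.json}. Output is deterministic:
#' two runs with the same seed produce byte-identical files.
#'
#' @param run an \code{"apneeg_run"}.
#' @param out_dir directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  lt <- lmm_results_table(run$lmm)
  if (!is.null(lt)) {
    utils::write.csv(lt, file.path(out_dir, "lmm_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lt, file.path(out_dir, "lmm_results.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  tt <- tmap_summary_table(run$tmaps)
  if (!is.null(tt))
    utils::write.csv(tt, file.path(out_dir, "tmap_summary.csv"),
                     row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.apneeg_run <- function(x, ...) {
  cn <- x$manifest$counts
  cat("apneeg pipeline run\n")
  cat(sprintf("  %d infants, seed %d\n", x$manifest$n_infants,
              x$manifest$seed))
  cat(sprintf("  candidates %d (apnoea %d, short %d); classified true %d; isolated %d; retained %d\n",
              cn$candidates, cn$apnoea, cn$short, cn$classified_true,
              cn$isolated, cn$epochs_retained))
  ret <- x$events[x$events$retained, ]
  if (nrow(ret))
    cat(sprintf("  mean EEG amplitude change (end-locked %g..%g s): %.4f log10 units\n",
                x$manifest$parameters$summary_window_s[1],
                x$manifest$parameters$summary_window_s[2],
                mean(ret$eeg_change, na.rm = TRUE)))
  for (nm in names(x$lmm))
    if (!is.null(x$lmm[[nm]]) && !x$lmm[[nm]]$categorical)
      cat(sprintf("  lmm %-11s beta1 = %+.5g (p = %.3g)\n", nm,
                  x$lmm[[nm]]$beta1[1], x$lmm[[nm]]$p_beta1))
  invisible(x)
}

#' @export
summary.apneeg_run <- function(object, ...) {
  print(object)
  tt <- tmap_summary_table(object$tmaps)
  if (!is.null(tt)) {
    cat("  t-map significant fractions:\n")
    for (i in seq_len(nrow(tt)))
      cat(sprintf("    %-13s %-11s n=%-3d frac=%.3f\n", tt$comparison[i],
                  tt$scope[i], tt$n_events[i], tt$frac_significant[i]))
  }
  invisible(object)
}
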