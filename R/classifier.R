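# Candidate-pause feature extraction and the logistic true-pause classifier
# with leave-one-infant-out cross-validation.

#' Extract classifier features for one candidate pause
#'
#' Computes the mean absolute value and standard deviation of the
#' SD-normalised thoracic trace in three windows: 10 to 1 s before the pause
#' start, 1 to 10 s after the pause end, and from 1 s after the start to 1 s
#' before the end. Normalisation by the full-recording SD makes the features
#' invariant to per-infant amplitude scaling.
#'
#' @param thorax thoracic respiration trace.
#' @param fs sampling rate in Hz.
#' @param event pause event (list/row with \code{start_s}, \code{end_s},
#'   \code{duration_s}).
#' @param recording_sd SD of the full recording's thoracic trace.
#' @return one-row data frame with \code{pre_meanabs, pre_sd, post_meanabs,
#'   post_sd, in_meanabs, in_sd}, or \code{NULL} when a window is truncated
#'   by a recording edge (such candidates are excluded).
#' @export
extract_features <- function(thorax, fs, event, recording_sd) {
  if (event$duration_s <= 2)
    stop("extract_features: pause duration must exceed 2 s")
  stopifnot(recording_sd > 0)
  n <- length(thorax)
  xn <- thorax / recording_sd
  win <- list(pre = c(event$start_s - 10, event$start_s - 1),
              post = c(event$end_s + 1, event$end_s + 10),
              inside = c(event$start_s + 1, event$end_s - 1))
  if (win$pre[1] < 0 || win$post[2] > n / fs) return(NULL)
  f <- lapply(win, function(wn) {
    idx <- time_window_idx(wn[1], wn[2], fs, n)
    if (length(idx) < 2) return(c(NA_real_, NA_real_))
    c(mean(abs(xn[idx])), stats::sd(xn[idx]))
  })
  data.frame(pre_meanabs = f$pre[1], pre_sd = f$pre[2],
             post_meanabs = f$post[1], post_sd = f$post[2],
             in_meanabs = f$inside[1], in_sd = f$inside[2])
}

FEATURE_COLS <- c("pre_meanabs", "pre_sd", "post_meanabs", "post_sd",
                  "in_meanabs", "in_sd")

#' Train the logistic true-pause classifier
#'
#' Fits an unregularised logistic regression of candidate label (true
#' cessation vs shallow breathing / artefact) on the six window features, and
#' evaluates it by leave-one-infant-out cross-validation: each fold holds out
#' every candidate of one infant, and balanced accuracy is reported per fold
#' and pooled over all held-out predictions.
#'
#' @param features data frame from [extract_features()] rows plus
#'   \code{label} (factor with levels false/true) and \code{infant_id}.
#' @return object of class \code{"pause_classifier"}: the fitted \code{glm},
#'   the CV report, and the feature column names.
#' @export
train_classifier <- function(features) {
  stopifnot(all(c(FEATURE_COLS, "label", "infant_id") %in% names(features)))
  features <- features[stats::complete.cases(features[FEATURE_COLS]), ]
  lab <- factor(features$label, levels = c("false", "true"))
  if (nlevels(droplevels(lab)) < 2)
    stop("train_classifier: both classes must be present")
  features$label <- lab
  infants <- unique(features$infant_id)
  fml <- stats::as.formula(paste("label ~", paste(FEATURE_COLS, collapse = " + ")))
  fit_on <- function(d) suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = d))

  if (length(infants) < 2) {
    warning("single infant: falling back to 5-fold CV")
    folds <- split(seq_len(nrow(features)),
                   rep_len(1:5, nrow(features)))
  } else {
    folds <- lapply(infants, function(id) which(features$infant_id == id))
    names(folds) <- infants
  }
  held_p <- rep(NA_real_, nrow(features))
  fold_ba <- rep(NA_real_, length(folds))
  for (k in seq_along(folds)) {
    te <- folds[[k]]
    m <- fit_on(features[-te, , drop = FALSE])
    p <- suppressWarnings(
      stats::predict(m, newdata = features[te, , drop = FALSE],
                     type = "response"))
    held_p[te] <- p
    truth_k <- features$label[te]
    if (nlevels(droplevels(truth_k)) == 2)
      fold_ba[k] <- balanced_accuracy(p > 0.5, truth_k == "true")
  }
  pooled <- balanced_accuracy(held_p > 0.5, features$label == "true")
  model <- fit_on(features)
  structure(list(model = model,
                 cv = list(fold_balanced_accuracy = fold_ba,
                           fold_ids = names(folds),
                           pooled_balanced_accuracy = pooled),
                 feature_cols = FEATURE_COLS,
                 n_candidates = nrow(features),
                 n_infants = length(infants)),
            class = "pause_classifier")
}

#' @export
print.pause_classifier <- function(x, ...) {
  cat(sprintf("Pause classifier: logistic regression on %d features, %d candidates, %d infants\n",
              length(x$feature_cols), x$n_candidates, x$n_infants))
  cat(sprintf("  LOIO balanced accuracy (pooled): %.3f\n",
              x$cv$pooled_balanced_accuracy))
  invisible(x)
}

#' @export
coef.pause_classifier <- function(object, ...) stats::coef(object$model)

#' Classify candidate pauses
#'
#' Applies a trained classifier to candidate features. The verdict is
#' \code{TRUE} (true pause) when the predicted probability exceeds 0.5; a
#' probability of exactly 0.5 is conservatively labelled \code{FALSE}.
#' Candidates with non-finite features are excluded (verdict \code{NA}).
#'
#' @param model a \code{"pause_classifier"}.
#' @param features data frame with the six feature columns.
#' @param threshold decision threshold on P(true).
#' @return data frame with \code{p_true} and logical \code{verdict}.
#' @export
classify <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "pause_classifier"))
  ok <- stats::complete.cases(features[model$feature_cols]) &
    apply(is.finite(as.matrix(features[model$feature_cols])), 1, all)
  p <- rep(NA_real_, nrow(features))
  if (any(ok))
    p[ok] <- suppressWarnings(
      stats::predict(model$model, newdata = features[ok, , drop = FALSE],
                     type = "response"))
  if (any(!ok))
    message(sum(!ok), " candidate(s) excluded: non-finite features")
  data.frame(p_true = p, verdict = ifelse(is.na(p), NA, p > threshold))
}

#' @export
predict.pause_classifier <- function(object, newdata, ...) {
  classify(object, newdata, ...)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity: insensitive to class imbalance, so a
#' degenerate all-positive predictor scores 0.5.
#'
#' @param pred logical (or coercible) predictions.
#' @param truth logical (or coercible) ground truth; both classes must occur.
#' @return scalar in [0, 1].
#' @export
balanced_accuracy <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  stopifnot(length(pred) == length(truth), !anyNA(truth))
  if (!any(truth) || all(truth))
    stop("balanced_accuracy: both classes must be present in truth")
  sens <- sum(pred & truth, na.rm = TRUE) / sum(truth)
  spec <- sum(!pred & !truth, na.rm = TRUE) / sum(!truth)
  (sens + spec) / 2
}
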