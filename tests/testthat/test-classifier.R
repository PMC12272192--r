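# Feature extraction and the logistic true-pause classifier.

sin_event <- list(start_s = 100, end_s = 110, duration_s = 10)

test_that("features follow the closed form for a unit sinusoid", {
  fs <- 25
  x <- tone(1, fs, 300)
  fe <- extract_features(x, fs, sin_event, recording_sd = sd(x))
  # mean|sin| = 2/pi; full-recording SD = 1/sqrt(2); ratio = 2*sqrt(2)/pi
  expect_equal(fe$in_meanabs, 2 * sqrt(2) / pi, tolerance = 0.01)
  expect_equal(fe$pre_meanabs, 2 * sqrt(2) / pi, tolerance = 0.01)
})

test_that("a silent pause gives zero in-window amplitude", {
  fs <- 25
  x <- tone(1, fs, 300)
  t <- (seq_along(x) - 1) / fs
  x[t >= 100 & t < 110] <- 0
  fe <- extract_features(x, fs, sin_event, recording_sd = sd(x))
  expect_equal(fe$in_meanabs, 0)
  expect_gt(fe$pre_meanabs, 0.5)
})

test_that("features are invariant to amplitude scaling", {
  fs <- 25
  set.seed(31)
  x <- tone(0.8, fs, 300) + rnorm(300 * fs, 0, 0.1)
  f1 <- extract_features(x, fs, sin_event, recording_sd = sd(x))
  f2 <- extract_features(7 * x, fs, sin_event, recording_sd = sd(7 * x))
  expect_equal(f1, f2)
})

test_that("degenerate windows are rejected or excluded", {
  fs <- 25
  x <- tone(1, fs, 300)
  expect_error(extract_features(x, fs, list(start_s = 100, end_s = 101.5,
                                            duration_s = 1.5), sd(x)),
               "duration")
  edge <- list(start_s = 5, end_s = 15, duration_s = 10)
  expect_null(extract_features(x, fs, edge, sd(x)))
})

test_that("balanced accuracy follows its definition", {
  expect_equal(balanced_accuracy(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
  pred <- c(rep(TRUE, 8), rep(FALSE, 2), rep(FALSE, 6), rep(TRUE, 4))
  truth <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(balanced_accuracy(pred, truth), 0.7)
  expect_equal(balanced_accuracy(rep(TRUE, 20), truth), 0.5)
  expect_error(balanced_accuracy(rep(TRUE, 3), rep(TRUE, 3)), "both classes")
})

make_sep_features <- function(n_per_infant = 20, n_infants = 4, gap = 1) {
  # classes fully separated in in_meanabs across all infants
  n <- n_per_infant * n_infants
  lab <- rep(c("true", "false"), length.out = n)
  base <- ifelse(lab == "true", 0.05, 0.05 + gap)
  data.frame(pre_meanabs = 0.9 + rnorm(n, 0, 0.05),
             pre_sd = 0.7 + rnorm(n, 0, 0.05),
             post_meanabs = 0.9 + rnorm(n, 0, 0.05),
             post_sd = 0.7 + rnorm(n, 0, 0.05),
             in_meanabs = base + runif(n, 0, 0.02),
             in_sd = base + runif(n, 0, 0.02),
             label = factor(lab, levels = c("false", "true")),
             infant_id = rep(sprintf("inf%02d", seq_len(n_infants)),
                             each = n_per_infant))
}

test_that("LOIO balanced accuracy is 1 for separable classes and ~0.5 under permutation", {
  set.seed(43)
  fe <- make_sep_features()
  m <- train_classifier(fe)
  expect_equal(m$cv$pooled_balanced_accuracy, 1.0)
  # folds partition candidates exactly by infant
  expect_setequal(m$cv$fold_ids, unique(fe$infant_id))

  perm <- make_sep_features(n_per_infant = 100)
  perm$label <- sample(perm$label)
  mp <- train_classifier(perm)
  expect_lt(abs(mp$cv$pooled_balanced_accuracy - 0.5), 0.12)
})

test_that("training requires both classes", {
  fe <- make_sep_features()
  fe$label <- factor("true", levels = c("false", "true"))
  expect_error(train_classifier(fe), "both classes")
})

test_that("generator candidates are classified with high LOIO balanced accuracy", {
  cfg <- quick_cfg(n_infants = 6, seed = 47)
  cand <- make_labelled_candidates(cfg, 100, 100)
  m <- train_classifier(cand)
  expect_gte(m$cv$pooled_balanced_accuracy, 0.9)
})

test_that("classification thresholds at 0.5 with a conservative tie-break", {
  set.seed(53)
  fe <- make_sep_features()
  m <- train_classifier(fe)
  v <- classify(m, fe)
  expect_equal(v$verdict, fe$label == "true")
  # the threshold comparison is strict: a probability equal to the
  # threshold is conservatively labelled false
  tie <- classify(m, fe, threshold = max(v$p_true))
  expect_false(any(tie$verdict))

  bad <- fe[1:2, ]
  bad$in_meanabs[1] <- NaN
  expect_message(v2 <- classify(m, bad), "excluded")
  expect_true(is.na(v2$verdict[1]))
})

test_that("a stiller chest never lowers the probability of a true pause", {
  set.seed(59)
  fe <- make_sep_features(n_per_infant = 50)
  m <- train_classifier(fe)
  expect_lt(coef(m)["in_meanabs"], 0)
  probe <- fe[rep(1, 11), ]
  probe$in_meanabs <- seq(1, 0, by = -0.1)
  p <- classify(m, probe)$p_true
  expect_true(all(diff(p) >= 0))
})
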