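# Respiration preprocessing, breath detection, pause extraction, the
# isolation filter, and baseline-window selection.

test_that("preprocessing removes DC and matches the closed-form high-pass response", {
  fs <- 25
  expect_true(all(abs(preprocess_respiration(rep(3, 1000), fs)) < 1e-6))

  x <- tone(1, fs, 120)
  y <- preprocess_respiration(x, fs, n_iter = 0)
  gain <- sqrt(2) * sqrt(mean(y[500:2500]^2))   # interior amplitude
  expect_lt(abs(gain / butter2_hp_gain2(1, 0.5) - 1), 0.01)
})

test_that("amplitude outliers are removed by iterated interpolation", {
  fs <- 25
  x <- tone(1, fs, 120)
  clean <- preprocess_respiration(x, fs)
  spiked <- x
  spiked[1500] <- 100 * sd(x)
  y <- preprocess_respiration(spiked, fs)
  near <- 1400:1600
  expect_lt(max(abs(y[near] - clean[near])), 0.05 * max(abs(clean)))
  expect_error(preprocess_respiration(c(x, NA), fs), "finite")
})

test_that("breath detection finds one breath per cycle with correct IBIs", {
  fs <- 25
  x <- tone(1, fs, 120)
  br <- detect_breaths(x, fs)
  expect_true(abs(length(br$breath_times) - 120) <= 1)
  expect_true(all(abs(br$ibis - 1) < 0.05))
})

test_that("zero signal yields zero breaths and short traces are rejected", {
  expect_length(detect_breaths(numeric(5000), 25)$breath_times, 0)
  expect_error(detect_breaths(numeric(100), 25), "short")
})

test_that("a silenced gap produces exactly one long inter-breath interval", {
  fs <- 25
  x <- tone(1, fs, 180)
  t <- (seq_along(x) - 1) / fs
  x[t >= 80 & t < 100] <- 0
  br <- detect_breaths(x, fs)
  expect_equal(sum(br$ibis > 15), 1)
  gap <- br$ibis[br$ibis > 15]
  expect_lt(abs(gap - 20), 1.5)
})

test_that("detection is invariant to amplitude scaling", {
  fs <- 25
  set.seed(41)
  x <- tone(0.8, fs, 300) + rnorm(300 * fs, 0, 0.05)
  b1 <- detect_breaths(x, fs)
  b2 <- detect_breaths(100 * x, fs)
  expect_equal(b1$breath_times, b2$breath_times)
})

test_that("pauses are extracted and categorised by duration", {
  br <- breath_series_from_times(cumsum(c(0, 1, 1, 20, 1)))
  pz <- find_pauses(br, 5, Inf)
  expect_equal(nrow(pz), 1)
  expect_equal(pz$duration_s, 20)
  expect_equal(pz$category, "apnoea")

  br2 <- breath_series_from_times(cumsum(c(0, 1, 6, 1)))
  pz2 <- find_pauses(br2, 5, 15)
  expect_equal(pz2$duration_s, 6)
  expect_equal(pz2$category, "short")

  br3 <- breath_series_from_times(cumsum(c(0, rep(1, 30))))
  expect_equal(nrow(find_pauses(br3, 5, Inf)), 0)
})

test_that("isolation flags match the spec'd cases and an O(n^2) oracle", {
  one <- data.frame(start_s = 300, end_s = 320, duration_s = 20)
  expect_true(filter_isolated(one, one)$isolated)

  two <- data.frame(start_s = c(100, 138), end_s = c(108, 146),
                    duration_s = c(8, 8))   # 30 s apart
  expect_equal(filter_isolated(two, two)$isolated, c(FALSE, FALSE))

  far <- data.frame(start_s = c(100, 308), end_s = c(108, 316),
                    duration_s = c(8, 8))   # 200 s apart
  expect_equal(filter_isolated(far, far)$isolated, c(TRUE, TRUE))

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    st <- sort(runif(n, 0, 2000))
    ev <- data.frame(start_s = st, end_s = st + runif(n, 5, 30))
    ev$duration_s <- ev$end_s - ev$start_s
    expect_equal(filter_isolated(ev, ev)$isolated, isolation_oracle(ev, ev))
  }
})

test_that("baseline window selection minimises the maximal inter-breath interval", {
  # uniform breathing: tie broken to the earliest grid window
  br <- breath_series_from_times(seq(0, 200, by = 1))
  ev <- list(start_s = 150)
  expect_equal(select_baseline_window(br, ev, 30, 15), c(60, 90))

  # a 4-s IBI ending 40 s before onset must be excluded by the chosen window
  times <- sort(c(seq(0, 106, by = 1), seq(110, 200, by = 1)))
  br2 <- breath_series_from_times(times)
  w <- select_baseline_window(br2, ev, 30, 15)
  expect_true(w[2] <= 106 || w[1] >= 110)

  # insufficient pre-event data
  expect_null(select_baseline_window(br, list(start_s = 50), 30, 15))

  # exhaustive independent oracle on random breath sets
  set.seed(13)
  for (rep in 1:10) {
    bt <- cumsum(runif(200, 0.5, 4))
    brr <- breath_series_from_times(bt)
    evr <- list(start_s = 150)
    w <- select_baseline_window(brr, evr, 10, 5)
    worst <- function(a) {
      ov <- bt[-length(bt)] < a + 10 & bt[-1] > a
      if (!any(ov)) Inf else max(diff(bt)[ov])
    }
    grid <- seq(150 - 90, 150 - 5 - 10, by = 1)
    best <- grid[which.min(vapply(grid, worst, numeric(1)))]
    expect_equal(w[1], best)
  }
})

test_that("selected windows beat the average candidate window", {
  set.seed(19)
  picked <- numeric(0); all_w <- numeric(0)
  for (rep in 1:20) {
    bt <- cumsum(runif(150, 0.5, 3.5))
    br <- breath_series_from_times(bt)
    w <- select_baseline_window(br, list(start_s = 140), 10, 5)
    worst <- function(a) {
      ov <- bt[-length(bt)] < a + 10 & bt[-1] > a
      if (!any(ov)) Inf else max(diff(bt)[ov])
    }
    picked <- c(picked, worst(w[1]))
    all_w <- c(all_w, vapply(seq(50, 125, 1), worst, numeric(1)))
  }
  expect_lt(median(picked), median(all_w))
})
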