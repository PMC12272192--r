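# Broadband filtering, epoching, amplitude screening, and the narrowband
# Hilbert time-frequency amplitude.

test_that("band-pass matches the closed-form Butterworth response on tones", {
  fs <- 250
  pass <- bandpass_eeg(tone(10, fs, 30), fs)
  amp <- sqrt(2) * sqrt(mean(pass[2000:5000]^2))
  expect_lt(abs(amp - 1), 0.05)

  rej <- bandpass_eeg(tone(50, fs, 30), fs)
  amp50 <- sqrt(2) * sqrt(mean(rej[2000:5000]^2))
  expect_lte(amp50, butter2_bp_gain2(50, 0.1, 30) + 0.01)
  expect_error(bandpass_eeg(c(1, NA, 3), fs), "finite")
})

test_that("filtering is zero-phase", {
  fs <- 250
  x <- tone(10, fs, 10)
  y <- bandpass_eeg(x, fs)
  cc <- ccf(x[500:2000], y[500:2000], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("epoching returns fixed windows and drops edge events", {
  fs <- 100
  eeg <- matrix(rnorm(1000 * fs), ncol = 1)
  ev <- data.frame(start_s = c(100, 50, 400), end_s = c(120, 70, 420))
  expect_message(
    ep <- epoch_eeg(eeg, fs, ev, lock = "start", window = c(-90, 150)),
    "dropped")
  expect_equal(ep$kept, c(1, 3))
  expect_equal(ep$dropped, 2)
  expect_equal(nrow(ep$epochs[[1]]), 240 * fs)
  expect_equal(range(attr(ep$epochs[[1]], "time_s")),
               c(-90, 150 - 1 / fs), tolerance = 0.02)
})

test_that("amplitude rejection is channel-wise at +/-500 uV", {
  ep1 <- matrix(rnorm(1000, 0, 100), ncol = 2)
  ep1[ep1 > 499] <- 499; ep1[ep1 < -499] <- -499
  ep2 <- ep1
  ep2[10, 1] <- 501
  ep3 <- ep1 + 1000
  keep <- reject_epochs(list(ep1, ep2, ep3))
  expect_equal(keep, matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                            ncol = 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("TFA of a unit tone is 0 log10 units at its band and low elsewhere", {
  fs <- 250
  x <- bandpass_eeg(tone(10.5, fs, 60), fs)
  a <- tfa(matrix(x, ncol = 1), fs)
  cfs <- attr(a, "cfs")
  interior <- seq(10 * fs, 50 * fs)
  at_band <- a[interior, which(cfs == 10.5), 1]
  expect_lt(max(abs(at_band)), 0.02)
  far <- which(abs(cfs - 10.5) >= 3)
  expect_true(all(colMeans(a[interior, far, 1, drop = FALSE]) <= -1))
})

test_that("silence hits the amplitude floor and short epochs are rejected", {
  fs <- 250
  a <- tfa(matrix(0, 20 * fs, 1), fs)
  expect_true(all(a == -6))
  expect_error(tfa(matrix(0, 5 * fs, 1), fs), "10 s")
})

test_that("an amplitude step is recovered as a log10(2) envelope step", {
  fs <- 250
  n <- 60 * fs
  amp <- rep(c(1, 0.5), each = n / 2)
  x <- amp * tone(10.5, fs, 60)
  a <- tfa(matrix(x, ncol = 1), fs)
  band <- which(attr(a, "cfs") == 10.5)
  first <- mean(a[seq(5 * fs, 25 * fs), band, 1])
  second <- mean(a[seq(35 * fs, 55 * fs), band, 1])
  expect_equal(first - second, log10(2), tolerance = 0.01)
})

test_that("scaling the signal shifts the TFA by log10(c)", {
  fs <- 250
  set.seed(61)
  x <- matrix(rnorm(30 * fs, 0, 20), ncol = 1)
  a1 <- tfa(x, fs)
  a3 <- tfa(3 * x, fs)
  expect_equal(a3, a1 + log10(3), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("narrowband envelope matches band power and a demodulation oracle", {
  fs <- 250
  set.seed(67)
  cf <- 10.5
  x <- bandpass_eeg(rnorm(40 * fs, 0, 10), fs)
  a <- tfa(matrix(x, ncol = 1), fs, cfs = cf)
  env_pkg <- 10^a[, 1, 1]
  interior <- seq(5 * fs, 35 * fs)
  # analytic-envelope identity: RMS(envelope) = sqrt(2) * RMS(band signal)
  bf <- signal::butter(2, c(cf - 1, cf + 1) / (fs / 2), "pass")
  xb <- signal::filtfilt(bf, x)
  expect_lt(abs(sqrt(mean(env_pkg[interior]^2)) /
                  (sqrt(2) * sqrt(mean(xb[interior]^2))) - 1), 0.05)
  # samplewise: the envelope tracks a complex-demodulation estimate
  t <- (seq_along(x) - 1) / fs
  z <- x * exp(-2i * pi * cf * t)
  lp <- signal::butter(2, 1 / (fs / 2), "low")
  env_dem <- 2 * Mod(complex(real = signal::filtfilt(lp, Re(z)),
                             imaginary = signal::filtfilt(lp, Im(z))))
  expect_gt(cor(env_pkg[interior], env_dem[interior]), 0.9)
})

test_that("change maps subtract baselines sample-wise or time-averaged", {
  a <- array(rnorm(100 * 29 * 2), c(100, 29, 2))
  attr(a, "time_s") <- seq(-5, 4.9, by = 0.1)
  same <- change_map(a, a)
  expect_true(all(same == 0))
  shifted <- change_map(a - 0.2, a)
  expect_true(all(abs(shifted + 0.2) < 1e-12))
  expect_error(change_map(a, array(0, c(50, 29, 2))), "shape")
  avg <- change_map(a, a, baseline_average = TRUE)
  expect_equal(dim(avg), dim(a))
  expect_equal(colMeans(avg[, , 1]), rep(0, 29), tolerance = 1e-12)
})
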