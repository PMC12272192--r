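# Paired t-maps, FDR control, change summaries, and the mixed-effects model.

test_that("paired t-map handles identical pairs and known offsets", {
  ev <- array(rnorm(20 * 10 * 3), c(20, 10, 3))
  tm0 <- ttest_map(ev, ev)
  expect_true(all(tm0$t == 0))
  expect_true(all(tm0$p == 1))
  expect_false(any(tm0$significant))

  set.seed(73)
  n <- 50
  base <- array(rnorm(n * 10 * 3, 0, 1), c(n, 10, 3))
  evs <- base - 0.2 + array(rnorm(n * 10 * 3, 0, 0.1), c(n, 10, 3))
  tm <- ttest_map(evs, base)
  # E[t] = -0.2 / (0.1 / sqrt(50)) ~ -14
  expect_lt(abs(mean(tm$t) - (-0.2 / (0.1 / sqrt(n)))), 3)
  expect_true(all(tm$n_pairs == n))
})

test_that("t-map is invariant to per-event constants added to both pair members", {
  set.seed(79)
  ev <- array(rnorm(15 * 8 * 2), c(15, 8, 2))
  bl <- array(rnorm(15 * 8 * 2), c(15, 8, 2))
  offs <- rnorm(15, 0, 10)
  ev2 <- ev + offs; bl2 <- bl + offs   # recycles along the first dimension
  t1 <- ttest_map(ev, bl); t2 <- ttest_map(ev2, bl2)
  expect_equal(t1$t, t2$t, tolerance = 1e-9)
})

test_that("samples with fewer than two pairs are masked", {
  ev <- array(rnorm(3 * 4), c(3, 4, 1))
  bl <- array(rnorm(3 * 4), c(3, 4, 1))
  ev[2:3, 1, 1] <- NA
  tm <- ttest_map(ev, bl)
  expect_true(is.na(tm$t[1, 1]))
  expect_equal(tm$n_pairs[1, 1], 1)
})

test_that("the BH mask matches hand-worked and brute-force step-up results", {
  expect_equal(fdr_mask(c(0.001, 0.2, 0.9), 0.01), c(TRUE, FALSE, FALSE))
  expect_false(any(fdr_mask(rep(1, 20), 0.01)))
  expect_true(all(fdr_mask(rep(1e-6, 20), 0.01)))

  set.seed(83)
  for (rep in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(fdr_mask(p, q), bh_bruteforce(p, q))
  }
  expect_length(fdr_mask(numeric(0)), 0)
})

test_that("change summaries average the stated window, frequencies, channels", {
  a <- array(-0.2, c(100, 29, 3))
  attr(a, "time_s") <- seq(-5, 4.9, by = 0.1)
  expect_equal(summarize_change(a), -0.2)
  b <- a
  b[attr(a, "time_s") >= 0, , ] <- 0
  attr(b, "time_s") <- attr(a, "time_s")
  expect_equal(summarize_change(b), -0.1)
  # rejected channel (all NA) is excluded, not contaminating
  a[, , 2] <- NA
  expect_equal(summarize_change(a), -0.2)
})

test_that("the mixed model recovers a noiseless linear relationship", {
  set.seed(89)
  d <- data.frame(x = rnorm(200),
                  infant_id = rep(sprintf("i%02d", 1:10), each = 20))
  d$eeg_change <- 2 * d$x
  m <- suppressWarnings(fit_lmm(d, "x"))
  expect_equal(unname(coef(m)["beta1"]), 2, tolerance = 1e-6)
  # variance components vanish (correlations are undefined at zero variance)
  expect_true(all(m$varcor$sdcor < 1e-3, na.rm = TRUE))
})

test_that("with zero random-effect variance the slope matches OLS", {
  d <- zero_ranef_data(seed = 97)
  m <- suppressWarnings(fit_lmm(d, "x"))
  ols <- coef(lm(eeg_change ~ x, data = d))[["x"]]
  expect_lt(abs(m$beta1 - ols) / abs(ols), 1e-6)
})

test_that("random-slope simulation is recovered and the fit is honest about structure", {
  d <- simulate_lmm_data(n_infants = 40, n_per_infant = 15, beta1 = 0.001,
                         slope_sd = 0.0005, intercept_sd = 0.02,
                         resid_sd = 0.05, seed = 101)
  m <- fit_lmm(d, "x")
  expect_lt(abs(m$beta1 - 0.001), 2 * m$se_beta1)
  expect_equal(m$random_structure, "intercept+slope")
  expect_equal(m$n_infants, 40)
  expect_lt(abs(mean(residuals(m))), 1e-6)
})

test_that("permuting the covariate gives null p-values", {
  set.seed(103)
  ps <- replicate(30, {
    d <- simulate_lmm_data(n_infants = 15, n_per_infant = 10, beta1 = 0.002,
                           seed = sample.int(1e6, 1))
    d$x <- sample(d$x)
    suppressWarnings(fit_lmm(d, "x"))$p_beta1
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lte(sum(ps < 0.05), 6)
})

test_that("categorical covariates use a joint fixed-effect test", {
  set.seed(107)
  d <- simulate_lmm_data(n_infants = 20, n_per_infant = 12, beta1 = 0,
                         seed = 109)
  d$state <- factor(sample(c("TA", "HVS", "ASI", "LVI"), nrow(d), TRUE))
  m <- suppressWarnings(fit_lmm(d, "state"))
  expect_true(m$categorical)
  expect_length(m$beta1, 3)
  expect_gte(m$p_beta1, 0)
  expect_error(fit_lmm(transform(d, z = 1), "z"), "zero variance")
})
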