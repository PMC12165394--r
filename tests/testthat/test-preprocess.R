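test_that("constant series pass through the filter unchanged", {
  x <- rep(0.85, 200)
  y <- lowpass_series(x, filter_spec(12, 120))
  expect_equal(y, x, tolerance = 1e-9)
})

test_that("passband amplitude is preserved and stopband attenuated", {
  rate <- 120
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  slow <- sin(2 * pi * 2 * t)
  fast <- 0.2 * sin(2 * pi * 50 * t)
  y <- lowpass_series(slow + fast, filter_spec(12, rate))
  amp2 <- fft_amplitude(y, 2, rate)
  amp50 <- fft_amplitude(y, 50, rate)
  expect_gt(amp2, 0.99)
  expect_lt(amp2, 1.01)
  expect_lt(amp50, 0.02)
})

test_that("filtering is zero-phase and idempotent for band-limited input", {
  rate <- 120
  t <- seq(0, 6 - 1 / rate, by = 1 / rate)
  x <- exp(-(t - 3)^2 / 0.5^2) # single slow bump, bandwidth well below cutoff/3
  spec <- filter_spec(12, rate)
  y1 <- lowpass_series(x, spec)
  y2 <- lowpass_series(y1, spec)
  # no phase lag: the bump peak stays on the same frame
  expect_lt(abs(t[which.max(y1)] - t[which.max(x)]), 1 / rate + 1e-12)
  expect_lt(max(abs(y2 - y1)), 0.01 * max(abs(y1)))
  expect_length(y1, length(x))
})

test_that("short NaN gaps are bridged, long ones rejected", {
  x <- sin(seq(0, 4, length.out = 400))
  x[100:103] <- NA
  expect_message(y <- lowpass_series(x, filter_spec(12, 120)),
                 class = "pdgait_log")
  expect_false(anyNA(y))
  x[200:260] <- NA
  expect_error(lowpass_series(x, filter_spec(12, 120)),
               class = "pdgait_format_error")
})

test_that("spline smoothing method is selectable and behaves as a low-pass", {
  rate <- 120
  t <- seq(0, 5 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 1 * t) + 0.05 * sin(2 * pi * 45 * t)
  y <- lowpass_series(x, filter_spec(12, rate, method = "spline"))
  expect_lt(fft_amplitude(y, 45, rate), 0.02)
  expect_gt(fft_amplitude(y, 1, rate), 0.95)
})

test_that("baseline statistic is the mean of the opening window", {
  rate <- 120
  x <- c(rep(0.55, 60), runif(100))
  expect_equal(baseline_stat(x, 0.5, rate), 0.55)
  ramp <- seq(0, 0.1, length.out = 60)
  expect_equal(baseline_stat(c(ramp, runif(50)), 0.5, rate), mean(ramp))
  expect_error(baseline_stat(x, 0, rate), class = "pdgait_config_error")
  expect_error(baseline_stat(x, 10, rate), class = "pdgait_config_error")
})
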