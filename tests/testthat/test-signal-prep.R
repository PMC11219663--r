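test_that("epoch resampling averages 12-s blocks and drops trailing partials", {
  rec <- tibble::tibble(time_s = 0:23, icp = 1:24, map = 90, amp = 1)
  es <- resample_epochs(rec)
  expect_equal(es$icp, c(6.5, 18.5))
  expect_equal(es$cpp, 90 - c(6.5, 18.5))
  expect_equal(es$t_mid_s, c(6, 18))

  const <- flat_recording(1, icp = 10)
  expect_true(all(resample_epochs(const)$icp == 10))

  rec30 <- tibble::tibble(time_s = 0:29, icp = 1:30, map = 90, amp = 1)
  expect_equal(nrow(resample_epochs(rec30)), 2)

  rec2s <- tibble::tibble(time_s = seq(0, 58, by = 2), icp = 1, map = 90, amp = 1)
  expect_error(resample_epochs(rec2s, epoch_s = 7), "multiple")
})

test_that("epochs with >50% missing samples are invalid, others tolerate gaps", {
  rec <- flat_recording(1, icp = 10)
  rec$icp[1:7] <- NA # 7 of 12 missing in epoch 1
  rec$icp[13:18] <- NA # 6 of 12 missing in epoch 2
  es <- resample_epochs(rec)
  expect_false(es$valid[1])
  expect_true(is.na(es$icp[1]))
  expect_true(es$valid[2])
  expect_equal(es$icp[2], 10)
})

test_that("epoch means conserve the grand mean over whole epochs", {
  set.seed(11)
  rec <- tibble::tibble(time_s = 0:599, icp = rnorm(600, 12, 3),
                        map = rnorm(600, 90, 5), amp = runif(600, 1, 2))
  es <- resample_epochs(rec)
  expect_equal(mean(es$icp), mean(rec$icp[1:600]), tolerance = 1e-12)
})

test_that("trailing moving average matches the stated convention", {
  expect_equal(smooth_moving_average(c(1, 2, 3, 4, 5), 4), c(1, 1.5, 2, 2.5, 3.5))
  expect_equal(smooth_moving_average(rep(7, 10), 4), rep(7, 10))
  expect_error(smooth_moving_average(1:5, 0), "span")

  # impulse response: bounded by max input, mass preserved away from edges,
  # and interior values equal the direct convolution
  x <- c(0, 0, 0, 0, 4, 0, 0, 0)
  sm <- smooth_moving_average(x, 4)
  expect_true(all(sm <= max(x)))
  conv <- as.numeric(stats::filter(x, rep(1 / 4, 4), sides = 1))
  expect_equal(sm[4:8], conv[4:8])
  expect_equal(sum(sm[5:8]), sum(x))

  # invalid entries propagate
  sm_na <- smooth_moving_average(c(1, NA, 3, 4, 5, 6), 2)
  expect_true(all(is.na(sm_na[2:3])))
  expect_false(anyNA(sm_na[4:6]))
})

test_that("window extraction keeps epochs by midpoint and re-zeroes time", {
  rec <- flat_recording(18, icp = 10)
  es <- resample_epochs(rec)
  expect_equal(nrow(extract_window(es, 0, 6)), 1800)
  w <- extract_window(es, 6, 18)
  expect_equal(nrow(w), 3600)
  expect_equal(w$t_mid_s[1], 6)
  expect_equal(attr(w, "t0_offset_s"), 6 * 3600)
  expect_error(extract_window(es, 20, 24), "no epochs")
  expect_error(extract_window(es, 6, 6), "start_h")
})

test_that("smoothing preserves the cpp = map - icp identity", {
  set.seed(4)
  rec <- tibble::tibble(time_s = 0:1199, icp = rnorm(1200, 12, 2),
                        map = rnorm(1200, 90, 4), amp = runif(1200, 1, 2))
  es <- smooth_epochs(resample_epochs(rec), 4)
  expect_equal(es$cpp, es$map - es$icp, tolerance = 1e-12)
})

test_that("pulse-amplitude extraction recovers the cardiac peak-to-trough", {
  fs <- 50
  t <- seq(0, 120, by = 1 / fs)
  pulse <- 10 + 2 * sin(2 * pi * 1 * t) # 1 Hz "cardiac" wave, amplitude 2
  amp <- extract_amp_from_pulse(pulse, fs)
  expect_true(all(abs(amp - 4) / 4 < 0.05))

  expect_lt(max(extract_amp_from_pulse(rep(10, 120 * fs), fs)), 1e-6)

  drift <- pulse + 3 * sin(2 * pi * t / 300) + 0.02 * t
  amp_d <- extract_amp_from_pulse(drift, fs)
  expect_true(all(abs(amp_d - amp) / amp < 0.05))

  expect_error(extract_amp_from_pulse(pulse, 10), "20 Hz")
  expect_error(extract_amp_from_pulse(pulse[1:100], fs), "60 s")
})
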