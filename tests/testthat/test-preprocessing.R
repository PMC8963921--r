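test_that("EMG envelope recovers amplitude of in-band activity and rejects out-of-band", {
  rate <- 2000
  t <- seq(0, 3, by = 1 / rate)
  interior <- which(t > 0.5 & t < 2.5)

  expect_equal(emg_envelope(numeric(6001), rate), numeric(6001))

  # in-band 200 Hz carrier, amplitude 1: rectified mean is 2/pi
  env <- emg_envelope(sin(2 * pi * 200 * t), rate)
  expect_equal(mean(env[interior]), 2 / pi, tolerance = 0.1)

  # below the 40 Hz band edge: strongly attenuated
  env_lo <- emg_envelope(sin(2 * pi * 5 * t), rate)
  expect_lt(max(env_lo[interior]), 0.05)
})

test_that("EMG envelope validates rate and sample finiteness", {
  expect_error(emg_envelope(numeric(1000), 800), class = "sts_rate_error")
  expect_error(emg_envelope(c(1, NA, numeric(100)), 2000), class = "sts_validation_error")
  expect_warning(emg_envelope(sin(seq(0, 50, by = 0.001)), 1000), "Nyquist")
})

test_that("envelopes are non-negative for arbitrary finite inputs", {
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(3000, sd = runif(1, 0.1, 10)) + runif(1, -2, 2)
    expect_true(all(emg_envelope(x, 2000) >= 0))
  }
})

test_that("force filtering keeps DC, attenuates ripple, and is zero-lag", {
  rate <- 2000
  expect_equal(filter_forces(rep(300, 1000), rate), rep(300, 1000),
               tolerance = 1e-6)

  t <- seq(0, 2, by = 1 / rate)
  x <- 300 + 5 * sin(2 * pi * 100 * t)
  y <- filter_forces(x, rate)
  interior <- which(t > 0.3 & t < 1.7)
  expect_equal(mean(y[interior]), 300, tolerance = 1e-3)
  expect_lt(max(abs(y[interior] - 300)), 5 / 20)  # > 20x ripple attenuation

  expect_error(filter_forces(numeric(0), rate), class = "sts_validation_error")

  # zero-lag contract: filtering the reversed signal and reversing equals
  # filtering the original (interior samples)
  set.seed(7)
  s <- cumsum(rnorm(2000)) / 10 + 100
  a <- filter_forces(s, rate)
  b <- rev(filter_forces(rev(s), rate))
  expect_equal(a[200:1800], b[200:1800], tolerance = 1e-9)
})

test_that("seat-off detection finds the first sub-threshold sample", {
  rate <- 1000
  # step from 300 N to 0 at t = 1 s
  f <- c(rep(300, 1000), rep(0, 2001))
  expect_equal(detect_seat_off(f, rate), 1.0)

  # linear ramp 300 -> 0 over [0, 3]: crosses 10 N at t = 2.9 s
  tt <- seq(0, 3, by = 1 / rate)
  ramp <- 300 * (1 - tt / 3)
  so <- detect_seat_off(ramp, rate)
  expect_equal(so, 2.9, tolerance = 2 / rate)

  expect_error(detect_seat_off(rep(300, 3000), rate), class = "sts_no_seat_off_error")
  expect_error(detect_seat_off(c(rep(5, 300), rep(300, 1000)), rate),
               class = "sts_invalid_loading_error")
})

test_that("trial segmentation cuts a 3 s window on a common grid", {
  rate_k <- 100; rate_f <- 2000
  ang <- data.frame(a = sin(seq(0, 10, by = 1 / rate_k)))
  frc <- data.frame(hip_v = rep(100, 10 * rate_f + 1))
  env <- data.frame(TA = abs(sin(seq(0, 10, by = 1 / rate_f))))

  pt <- segment_trial(env, rate_f, ang, rate_k, frc, rate_f, seat_off_time = 5)
  expect_equal(pt$window, c(4, 7))
  expect_length(pt$time, 301)
  expect_equal(nrow(pt$envelopes), 301)
  expect_equal(nrow(pt$joint_angles), 301)
  expect_length(pt$progress, 101)
  expect_equal(nrow(pt$progress_grid$envelopes), 101)

  expect_error(
    segment_trial(env, rate_f, ang, rate_k, frc, rate_f, seat_off_time = 0.5),
    class = "sts_truncation_error")
})

test_that("segmenting an already segmented window is idempotent", {
  rate <- 100
  tt <- seq(0, 3, by = 1 / rate)
  env <- data.frame(TA = abs(sin(2 * pi * tt)))
  ang <- data.frame(a = cos(tt), b = sin(tt), c = tt, d = tt^2)
  frc <- data.frame(hip_v = pmax(300 * (1 - tt), 0))
  pt1 <- segment_trial(env, rate, ang, rate, frc, rate, seat_off_time = 1)
  pt2 <- segment_trial(pt1$envelopes, rate, pt1$joint_angles, rate,
                       pt1$forces, rate, seat_off_time = 1)
  expect_equal(pt2$envelopes, pt1$envelopes, tolerance = 1e-12)
  expect_equal(pt2$joint_angles, pt1$joint_angles, tolerance = 1e-12)
})

test_that("MVC normalization divides by the reference and flags overshoot", {
  env <- c(0, 0.2, 0.5)
  expect_equal(max(mvc_normalize(env, 0.5)), 1.0)
  expect_equal(mvc_normalize(numeric(10), 0.3), numeric(10))
  expect_warning(out <- mvc_normalize(c(0.2, 1.0), 0.5), "exceeds 1")
  expect_equal(max(out), 2.0)
  expect_error(mvc_normalize(env, 0), class = "sts_validation_error")
})
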