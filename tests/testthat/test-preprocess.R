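test_that("segmentation emits exactly the windows that fit, at exact offsets", {
  x <- matrix(rnorm(12000 * 2), ncol = 2)
  seg <- segment_trial(x, fs = 1000, window_s = 1, step_s = 0.25)
  expect_equal(nrow(seg), 45)
  expect_equal(seg$start, seq(0, by = 250, length.out = 45))
  expect_identical(seg$data[[3]], x[501:1500, ])

  expect_equal(nrow(segment_trial(x, 1000, 1, 1)), 12)
  expect_equal(nrow(segment_trial(matrix(rnorm(500), ncol = 1), 1000, 1, 0.25)), 0)
  expect_error(segment_trial(x, 1000, 1, 0.2505), "integer point counts")
})

test_that("polynomial detrending removes a model-matched trend and is idempotent", {
  t <- seq_len(1000)
  u <- (t - 500.5) / 500
  p <- 3 - 2 * u + 0.5 * u^2 + u^3 - 4 * u^4
  expect_lt(max(abs(remove_trend(p))), 1e-6 * max(abs(p)))
  expect_true(all(remove_trend(rep(0, 1000)) == 0))

  # quartic + sinusoid: residual matches a least-squares oracle on the
  # same basis within 1% RMS of the sinusoid
  s <- sin(2 * pi * 20 * (t - 1) / 1000)
  res <- remove_trend(p + s)
  oracle <- stats::residuals(stats::lm(y ~ stats::poly(t, 4),
                                       data = list(y = p + s, t = t)))
  expect_lt(sqrt(mean((res - oracle)^2)), 1e-8)
  # the detrend costs the sinusoid less than 1% of its RMS power
  expect_lt(abs(sqrt(mean(res^2)) - sqrt(mean(s^2))), 0.01 * sqrt(mean(s^2)))

  set.seed(42)
  x <- rnorm(1000) + p
  once <- remove_trend(x)
  expect_lt(max(abs(remove_trend(once) - once)), 1e-6 * max(abs(once)))

  expect_error(remove_trend(rnorm(5), degree = 4), "too short")
})

test_that("high-pass Butterworth matches its closed-form magnitude response", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  gain_db <- function(f0) {
    x <- sin(2 * pi * f0 * t)
    y <- highpass_filter(x, fs, cutoff = 10, order = 4)
    20 * log10(tone_amplitude(y, fs) / tone_amplitude(x, fs))
  }
  expect_lt(abs(gain_db(10) - (-3.01)), 0.3)
  expect_lt(gain_db(2.5), -45)           # closed form: -48.2 dB
  expect_lt(abs(gain_db(100)), 0.5)
  expect_error(highpass_filter(rnorm(100), fs, cutoff = 600), "Nyquist")
})

test_that("the adaptive notch removes strong lines and leaves clean signal alone", {
  fs <- 1000
  t1 <- (0:999) / fs
  x <- sin(2 * pi * 30 * t1) + 5 * sin(2 * pi * 50 * t1 + 0.7)
  y <- adaptive_notch(x, fs)
  expect_equal(attr(y, "triggered")[[1]], 50)
  sx <- abs(fft(x))[2:501]; sy <- abs(fft(y))[2:501]
  expect_lt(sy[50] / sx[50], 0.1)
  expect_lt(abs(sy[30] / sx[30] - 1), 0.05)

  # no line component: output identical to input
  set.seed(7)
  z <- rnorm(1000)
  zy <- adaptive_notch(z, fs)
  expect_equal(unname(as.numeric(zy)), z)
  expect_length(attr(zy, "triggered")[[1]], 0)

  # two contaminated harmonics
  x2 <- rnorm(1000, sd = 0.2) + 4 * sin(2 * pi * 50 * t1) +
    3 * sin(2 * pi * 150 * t1 + 1)
  y2 <- adaptive_notch(x2, fs)
  expect_equal(attr(y2, "triggered")[[1]], c(50, 150))
  s2 <- abs(fft(x2))[2:501]; sy2 <- abs(fft(y2))[2:501]
  expect_lt(sy2[50] / s2[50], 0.1)
  expect_lt(sy2[150] / s2[150], 0.1)
})

test_that("rejection flags only windows whose residual line survives the notch", {
  fs <- 1000
  set.seed(8)
  clean <- matrix(rnorm(2000), ncol = 2)
  expect_false(reject_sample(clean, fs))

  t1 <- (0:999) / fs
  dirty <- rnorm(1000, sd = 0.05) + 10 * sin(2 * pi * 50 * t1)
  expect_true(reject_sample(dirty, fs))
  expect_false(reject_sample(dirty, fs, threshold = Inf))
})

test_that("the full cleaning chain preserves the muscle-signal band energies", {
  # same seed with and without contamination: channel 1's band-shaped
  # component is drawn first and therefore identical in both trials
  spec_dirty <- study_spec(trial_duration = 4, drift_amplitude = 5,
                           line_amplitude = c(0.5, 0.5, 2, 2, 2, 2),
                           sensor_noise = 0, seed = 11)
  spec_clean <- study_spec(trial_duration = 4, drift_amplitude = 0,
                           line_amplitude = rep(0, 6),
                           sensor_noise = 0, seed = 11)
  study_d <- segment_windows(generate_study(spec_dirty)[1, ])
  study_c <- segment_windows(generate_study(spec_clean)[1, ])
  wd <- preprocess_windows(study_d)
  wc <- preprocess_windows(study_c)

  bands <- spectral_bands()
  harmonics <- seq(50, 450, by = 50)
  for (i in c(1, 7, 13)) {
    fd <- abs(fft(wd$data[[i]][, 1]))[2:501]
    fc <- abs(fft(wc$data[[i]][, 1]))[2:501]
    for (b in which(bands$low >= 10 & bands$high <= 400)) {
      idx <- bands$low[b]:(bands$high[b] - 1)
      idx <- idx[!vapply(idx, function(f) any(abs(f - harmonics) <= 2), logical(1))]
      ratio <- sum(fd[idx]^2) / sum(fc[idx]^2)
      expect_gt(ratio, 0.9)
      expect_lt(ratio, 1.1)
    }
  }
})

test_that("preprocessing keeps shapes and metadata and only flags rejection", {
  spec <- study_spec(trial_duration = 2, seed = 3)
  w <- segment_windows(generate_study(spec)[1:2, ])
  out <- preprocess_windows(w)
  expect_identical(dim(out$data[[1]]), dim(w$data[[1]]))
  expect_identical(out[c("trial", "subject", "session", "taste", "window")],
                   w[c("trial", "subject", "session", "taste", "window")])
  expect_type(out$rejected, "logical")
})
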