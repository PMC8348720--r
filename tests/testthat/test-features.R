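test_that("the amplitude spectrum matches a direct DFT and basic signals", {
  fs <- 1000
  f <- amplitude_spectrum(cos(2 * pi * 25 * (0:999) / fs), fs)
  expect_equal(which.max(f), 25)
  expect_equal(attr(f, "resolution"), 1)

  expect_lt(max(amplitude_spectrum(rep(3, 1000), fs)), 1e-9)
  expect_error(amplitude_spectrum(rnorm(999), fs), "even")

  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(64)
    expect_rel_equal(as.numeric(amplitude_spectrum(x, 64)),
                     brute_dft_amplitude(x), 1e-8)
  }
})

test_that("band averages follow the 13-band index arithmetic", {
  flat <- rep(1, 500); attr(flat, "resolution") <- 1
  expect_true(all(band_average_features(flat) == 1))

  ind <- rep(0, 500); ind[10:19] <- 1; attr(ind, "resolution") <- 1
  b <- band_average_features(ind)
  expect_equal(unname(b[1]), 1)
  expect_true(all(b[-1] == 0))

  ramp <- as.numeric(1:500); attr(ramp, "resolution") <- 1
  r <- band_average_features(ramp)
  expect_equal(unname(r["band_10_20"]), 14.5)
  expect_equal(unname(r["band_100_200"]), 149.5)

  half <- rep(1, 250); attr(half, "resolution") <- 2
  expect_error(band_average_features(half), "1 Hz resolution")
})

test_that("spectral moments satisfy their defining identities", {
  line <- rep(0, 500); line[50] <- 3; attr(line, "resolution") <- 1
  expect_equal(unname(spectral_shape_features(line)), c(50, 50, 0))

  two <- rep(0, 500); two[c(10, 30)] <- 1; attr(two, "resolution") <- 1
  s <- spectral_shape_features(two)
  expect_equal(unname(s["fc"]), 20)
  expect_equal(unname(s["rvf"]), 10)
  expect_equal(unname(s["rmsf"]), sqrt(500))

  lit <- spectral_shape_features(two, literal_equations = TRUE)
  expect_equal(unname(lit["rmsf"]), 500)
  expect_equal(unname(lit["rvf"]), 100)

  set.seed(6)
  for (i in 1:20) {
    f <- runif(500); attr(f, "resolution") <- 1
    s <- spectral_shape_features(f)
    expect_rel_equal(s["rmsf"]^2, s["rvf"]^2 + s["fc"]^2, 1e-8)
  }

  zero <- rep(0, 500); attr(zero, "resolution") <- 1
  expect_error(spectral_shape_features(zero), "all-zero")
})

test_that("time-domain features match their definitions", {
  const <- rep(2, 100)
  td <- time_domain_features(const, types = c("rms", "zcr", "mav"))
  expect_equal(unname(td), c(2, 0, 2))
  expect_error(time_domain_features(const), "sigma = 0")

  alt <- rep(c(1, -1), 5)
  expect_equal(unname(time_domain_features(alt, types = "zcr")), 9)

  expect_equal(unname(time_domain_features(rep(c(3, -3), 50),
                                           types = "rms",
                                           literal_equations = TRUE)), 9)

  set.seed(99)
  g <- rnorm(1e6)
  td <- time_domain_features(g, types = c("kurtosis", "skewness"))
  expect_lt(abs(td["kurtosis"] - 3), 0.05)
  expect_lt(abs(td["skewness"]), 0.05)
})

test_that("every feature matches the direct-summation oracle on random windows", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(1000) + 0.3 * sin(2 * pi * 40 * (0:999) / 1000)
    w <- tibble::tibble(subject = 1, session = 1, taste = factor("Sour", taste_levels()),
                        window = 1, fs = 1000, data = list(matrix(x, ncol = 1)))
    got <- extract_features(w)
    vals <- as.numeric(got[1, paste0("ch1_", feature_types()$feature_type)])
    expect_rel_equal(vals, unname(oracle_features(x, 1000)), 1e-8)
  }
})

test_that("feature vectors have channel-major layout and the documented sizes", {
  spec <- quiet_spec(sessions_per_subject = 1)
  w <- preprocess_windows(segment_windows(generate_study(spec)))
  full <- extract_features(w)
  cols <- feature_columns(full)
  expect_equal(nrow(cols), 126)
  # channel-major: channels ascending, 21 canonical types within channel
  expect_equal(cols$channel, rep(1:6, each = 21))
  expect_equal(cols$type_index, rep(1:21, times = 6))

  red <- extract_features(w, channels = c(2, 3, 4, 6),
                          types = c("band_100_200", "band_200_300",
                                    "band_300_400", "rvf"))
  expect_equal(nrow(feature_columns(red)), 16)

  one <- extract_features(w, channels = 3, types = "rms")
  expect_equal(feature_columns(one)$column, "ch3_rms")

  expect_error(extract_features(w, channels = integer(0)), "empty")
  expect_error(extract_features(w, types = "wavelength"), "unknown feature type")
})

test_that("subsetting features filters columns only, and composes", {
  spec <- quiet_spec(sessions_per_subject = 1)
  w <- preprocess_windows(segment_windows(generate_study(spec)))
  full <- extract_features(w)

  expect_identical(subset_features(full), full)
  top4 <- subset_features(full, types = c("band_100_200", "band_200_300",
                                          "band_300_400", "rvf"))
  expect_equal(nrow(feature_columns(top4)), 24)
  expect_equal(nrow(top4), nrow(full))

  two_step <- subset_features(subset_features(full, types = c("rms", "mav")),
                              channels = c(1, 5))
  one_step <- subset_features(full, types = c("rms", "mav"), channels = c(1, 5))
  expect_identical(two_step, one_step)

  expect_error(subset_features(full, channels = 9), "not in dataset")
  expect_error(subset_features(top4, types = "rms"), "not in dataset")
})

test_that("features scale as expected under signal amplification", {
  set.seed(13)
  x <- rnorm(1000)
  w <- function(v) tibble::tibble(subject = 1, session = 1,
                                  taste = factor("Sour", taste_levels()),
                                  window = 1, fs = 1000,
                                  data = list(matrix(v, ncol = 1)))
  f1 <- extract_features(w(x)); f3 <- extract_features(w(3 * x))
  scale_cov <- c(spectral_bands()$name, "rms", "mav")
  invariant <- c("fc", "rmsf", "rvf", "zcr", "kurtosis", "skewness")
  for (ft in scale_cov) {
    expect_rel_equal(f3[[paste0("ch1_", ft)]], 3 * f1[[paste0("ch1_", ft)]], 1e-8)
  }
  for (ft in invariant) {
    expect_rel_equal(f3[[paste0("ch1_", ft)]], f1[[paste0("ch1_", ft)]], 1e-8)
  }
})
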