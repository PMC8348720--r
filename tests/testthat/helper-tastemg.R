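# Shared fixtures and independent oracles.

# A clean, fast study spec: short trials, no drift / interference / sensor
# noise unless asked for. Defaults otherwise follow study_spec().
quiet_spec <- function(..., trial_duration = 2, drift_amplitude = 0,
                       line_amplitude = rep(0, 6), sensor_noise = 0) {
  study_spec(trial_duration = trial_duration,
             drift_amplitude = drift_amplitude,
             line_amplitude = line_amplitude,
             sensor_noise = sensor_noise, ...)
}

# Profiles where every class excites only one spectral band (no class
# contrast): used for the spectral-shaping oracle.
single_band_profiles <- function(band, gain = 1, n_channels = 6) {
  g <- matrix(0, n_channels, 13)
  g[, band] <- gain
  profiles <- lapply(taste_levels(), function(tl) taste_profile(tl, g))
  names(profiles) <- taste_levels()
  profiles
}

# Profiles whose class contrast lives only in the 100-400 Hz bands of the
# given channel pair, with complementary coding: the first channel only
# separates coarse tiers (three groups of two classes) and the second only
# splits within tiers, so no single channel suffices and the pair is the
# uniquely best 2-channel subset.
planted_profiles <- function(channels, n_channels = 6) {
  stopifnot(length(channels) == 2)
  tier <- c(None = 0.3, Bitter = 0.3, Sweet = 1.2, Umami = 1.2,
            Sour = 3, Salty = 3)
  split <- c(None = 0.3, Bitter = 2, Sweet = 0.3, Umami = 2,
             Sour = 0.3, Salty = 2)
  profiles <- lapply(taste_levels(), function(tl) {
    g <- matrix(0, n_channels, 13)
    g[, 1:9] <- 1
    g[, 10:12] <- 0.3
    g[, 13] <- 0.2
    g[channels[1], 10:12] <- tier[[tl]]
    g[channels[2], 10:12] <- split[[tl]]
    taste_profile(tl, g)
  })
  names(profiles) <- taste_levels()
  profiles
}

# O(L^2) DFT magnitude oracle (one-sided, DC excluded).
brute_dft_amplitude <- function(x) {
  L <- length(x)
  vapply(1:(L / 2), function(i) {
    k <- 0:(L - 1)
    Mod(sum(x * exp(-2i * pi * i * k / L)))
  }, numeric(1))
}

# Direct-summation oracle for all 21 feature types, written straight from
# the defining sums with plain loops; independent of the package's
# vectorized implementations (shares only the FFT input).
oracle_features <- function(x, fs) {
  L <- length(x)
  f <- abs(fft(x))[2:(L / 2 + 1)]
  out <- numeric(21)
  for (n in 1:9) {
    s <- 0
    for (i in (n * 10):((n + 1) * 10 - 1)) s <- s + f[i]
    out[n] <- s / 10
  }
  for (n in 10:13) {
    s <- 0
    for (i in ((n - 9) * 100):((n - 8) * 100 - 1)) s <- s + f[i]
    out[n] <- s / 100
  }
  num <- 0; den <- 0; num2 <- 0
  for (i in 1:(L / 2)) {
    num <- num + f[i] * (i * fs / L)
    num2 <- num2 + f[i] * (i * fs / L)^2
    den <- den + f[i]
  }
  fc <- num / den
  out[14] <- fc
  out[15] <- sqrt(num2 / den)
  num3 <- 0
  for (i in 1:(L / 2)) num3 <- num3 + f[i] * (i * fs / L - fc)^2
  out[16] <- sqrt(num3 / den)
  out[17] <- sqrt(sum(x^2) / L)
  z <- 0
  for (i in 1:(L - 1)) if (x[i] * x[i + 1] < 0) z <- z + 1
  out[18] <- z
  out[19] <- sum(abs(x)) / L
  mu <- sum(x) / L
  sigma <- sqrt(sum((x - mu)^2) / L)
  out[20] <- sum(((x - mu) / sigma)^4) / L
  out[21] <- sum(((x - mu) / sigma)^3) / L
  names(out) <- feature_types()$feature_type
  out
}

# Steady-state amplitude of a filtered tone: RMS over the signal after
# discarding the first `discard_s` seconds, scaled to a sine amplitude.
tone_amplitude <- function(x, fs, discard_s = 2) {
  tail_x <- x[(discard_s * fs + 1):length(x)]
  sqrt(mean(tail_x^2)) * sqrt(2)
}

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}

# Evaluate expr under a temporary seed, restoring the RNG state after.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
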