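#' Specify a synthetic sEMG taste study
#'
#' Describes a multi-subject, multi-session recording campaign in which each
#' session holds one 12 s trial per taste class, captured on `n_channels`
#' channels at 1000 Hz. Each trial is synthesised as band-shaped Gaussian
#' noise (per-band spectral amplitude = profile gain x `noise_floor`), plus
#' a random quartic baseline drift, 50 Hz power-line interference with
#' geometrically decaying harmonics, and broadband sensor noise.
#'
#' Channels 1 and 2 model a differential electrode pair and must receive a
#' line-interference amplitude no larger than any single-ended channel,
#' reflecting the common-mode rejection of differential recording.
#'
#' @param n_subjects Number of subjects.
#' @param sessions_per_subject Sessions recorded per subject; each session
#'   contains exactly one trial per taste, in randomized order.
#' @param trial_duration Trial length in seconds (default 12).
#' @param sampling_rate Sampling frequency in Hz (default 1000).
#' @param profiles Six [taste_profile()] objects (default
#'   [default_taste_profiles()]).
#' @param drift_degree Polynomial degree of the baseline drift (default 4).
#' @param drift_amplitude Scale (SD) of the random drift coefficients, in
#'   signal units.
#' @param line_amplitude Per-channel amplitude of the 50 Hz fundamental.
#' @param harmonic_decay Geometric decay factor for successive harmonics.
#' @param max_harmonic Highest interference harmonic, in Hz.
#' @param noise_floor Broadband amplitude multiplying all band gains.
#' @param sensor_noise SD of the additive white sensor noise.
#' @param seed Integer seed from which all trial and ordering randomness is
#'   derived.
#' @return An object of class `study_spec`.
#' @export
#' @examples
#' spec <- study_spec(n_subjects = 1, sessions_per_subject = 2)
#' spec$n_channels
study_spec <- function(n_subjects = 1,
                       sessions_per_subject = 2,
                       trial_duration = 12,
                       sampling_rate = 1000,
                       profiles = default_taste_profiles(),
                       drift_degree = 4,
                       drift_amplitude = 5,
                       line_amplitude = c(0.5, 0.5, 2, 2, 2, 2),
                       harmonic_decay = 0.5,
                       max_harmonic = 450,
                       noise_floor = 1,
                       sensor_noise = 0.15,
                       seed = 1) {
  n <- trial_duration * sampling_rate
  if (abs(n - round(n)) > 1e-9) {
    abort("sampling_rate x trial_duration must be an integer sample count")
  }
  n_channels <- nrow(profiles[[1]]$band_gain)
  profiles <- validate_profiles(profiles, n_channels)
  if (length(line_amplitude) == 1) {
    line_amplitude <- rep(line_amplitude, n_channels)
  }
  if (length(line_amplitude) != n_channels) {
    abort("line_amplitude must have one value per channel")
  }
  if (n_channels >= 3 &&
      max(line_amplitude[1:2]) > min(line_amplitude[3:n_channels])) {
    abort(paste("differential channels 1 and 2 must receive line interference",
                "no stronger than the single-ended channels"))
  }
  if (max_harmonic >= sampling_rate / 2) {
    abort("max_harmonic must be below the Nyquist frequency")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    sessions_per_subject = as.integer(sessions_per_subject),
    trial_duration = trial_duration,
    sampling_rate = sampling_rate,
    n_channels = n_channels,
    profiles = profiles,
    drift_degree = as.integer(drift_degree),
    drift_amplitude = drift_amplitude,
    line_amplitude = line_amplitude,
    harmonic_decay = harmonic_decay,
    max_harmonic = max_harmonic,
    noise_floor = noise_floor,
    sensor_noise = sensor_noise,
    seed = as.integer(seed)
  ), class = "study_spec")
}

# Deterministic per-(subject, session, taste) seed below 2^31.
trial_seed <- function(spec, subject, session, taste_index) {
  base <- (as.double(spec$seed) * 1000003 + subject * 30011 +
             session * 977 + taste_index * 53)
  as.integer(base %% .Machine$integer.max)
}

# Per-channel gain over the one-sided frequency grid implied by n and fs.
band_gain_vector <- function(gains, freqs) {
  bands <- spectral_bands()
  g <- numeric(length(freqs))
  for (b in seq_len(nrow(bands))) {
    sel <- freqs >= bands$low[b] & freqs < bands$high[b]
    g[sel] <- gains[b]
  }
  g
}

#' Generate one synthetic trial
#'
#' Synthesises a single `channels x duration` recording for one
#' (subject, session, taste) cell. Band-shaped noise is produced by scaling
#' the discrete Fourier transform of white Gaussian noise with the
#' profile's per-band gains and inverting the transform, which gives exact
#' control over band energies. The result is deterministic given the
#' specification seed and the identifiers.
#'
#' @param spec A [study_spec()].
#' @param subject,session Integer identifiers.
#' @param taste A taste label with a profile in `spec`.
#' @return Numeric matrix, samples x channels, with columns `ch1..chC`.
#' @export
#' @examples
#' spec <- study_spec(trial_duration = 2)
#' x <- generate_trial(spec, 1, 1, "Sour")
#' dim(x)
generate_trial <- function(spec, subject, session, taste) {
  taste <- as.character(as_taste(taste))
  prof <- spec$profiles[[taste]]
  if (is.null(prof)) abort(sprintf("no profile for taste '%s'", taste))

  fs <- spec$sampling_rate
  n <- as.integer(round(spec$trial_duration * fs))
  tt <- (seq_len(n) - 1) / fs
  freqs_full <- abs(c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)) * fs / n

  seed <- trial_seed(spec, subject, session, match(taste, taste_levels()))
  out <- withr_seed(seed, {
    x <- matrix(0, n, spec$n_channels)
    for (ch in seq_len(spec$n_channels)) {
      # band-shaped component
      g <- band_gain_vector(prof$band_gain[ch, ] * spec$noise_floor, freqs_full)
      if (any(g > 0)) {
        z <- fft(rnorm(n)) * g
        x[, ch] <- Re(fft(z, inverse = TRUE)) / n
      }
      # quartic (or configured-degree) baseline drift on normalized time
      if (spec$drift_amplitude > 0) {
        u <- 2 * tt / spec$trial_duration - 1
        coef <- rnorm(spec$drift_degree + 1, sd = spec$drift_amplitude)
        x[, ch] <- x[, ch] + drop(outer(u, 0:spec$drift_degree, `^`) %*% coef)
      }
      # power-line fundamental plus harmonics
      if (spec$line_amplitude[ch] > 0) {
        ks <- seq(50, spec$max_harmonic, by = 50) / 50
        for (k in ks) {
          amp <- spec$line_amplitude[ch] * spec$harmonic_decay^(k - 1)
          x[, ch] <- x[, ch] + amp * sin(2 * pi * 50 * k * tt + runif(1, 0, 2 * pi))
        }
      }
      # white sensor noise
      if (spec$sensor_noise > 0) {
        x[, ch] <- x[, ch] + rnorm(n, sd = spec$sensor_noise)
      }
    }
    x
  })
  colnames(out) <- paste0("ch", seq_len(spec$n_channels))
  out
}

# Evaluate expr under a local RNG seed without touching the global stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a full synthetic study
#'
#' Produces every trial of the study: `n_subjects x sessions_per_subject`
#' sessions, each containing one trial per taste in an order randomized by
#' the specification seed.
#'
#' @param spec A [study_spec()].
#' @return A tibble with one row per trial and columns `trial`, `subject`,
#'   `session`, `taste` (factor), `fs` and `data` (list of samples x
#'   channels matrices).
#' @export
#' @examples
#' study <- generate_study(study_spec(trial_duration = 2))
#' dplyr::count(study, taste)
generate_study <- function(spec) {
  grid <- expand.grid(session = seq_len(spec$sessions_per_subject),
                      subject = seq_len(spec$n_subjects))
  rows <- purrr::pmap(grid, function(session, subject) {
    order_seed <- trial_seed(spec, subject, session, 0L)
    tastes <- withr_seed(order_seed, sample(taste_levels()))
    tibble(
      subject = subject, session = session,
      taste = as_taste(tastes),
      data = lapply(tastes, function(tl) generate_trial(spec, subject, session, tl))
    )
  })
  out <- bind_rows(rows)
  out$fs <- spec$sampling_rate
  out$trial <- seq_len(nrow(out))
  select(out, trial, subject, session, taste, fs, data)
}
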