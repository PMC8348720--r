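#' One-sided amplitude spectrum
#'
#' Magnitude of the length-`L` discrete Fourier transform at bins
#' `1 .. L/2` (DC excluded), unscaled. Bin `i` corresponds to frequency
#' `i * fs / L` Hz, so a 1 s window at 1000 Hz has 1 Hz resolution and the
#' bin index equals the frequency in Hz.
#'
#' @param x Single-channel signal of even length.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `L/2` with attribute `resolution`
#'   (`fs/L`, in Hz).
#' @export
#' @examples
#' f <- amplitude_spectrum(cos(2 * pi * 25 * (0:999) / 1000), 1000)
#' which.max(f)
amplitude_spectrum <- function(x, fs) {
  L <- length(x)
  if (L %% 2 != 0) abort("amplitude_spectrum requires an even window length")
  f <- abs(fft(x))[2:(L / 2 + 1)]
  attr(f, "resolution") <- fs / L
  f
}

spectrum_resolution <- function(f, resolution = NULL) {
  res <- resolution %||% attr(f, "resolution")
  if (is.null(res)) abort("spectrum resolution unknown; pass `resolution`")
  res
}

#' Spectral band-average features
#'
#' The 13 band features: mean one-sided spectrum amplitude over each of the
#' nine 10 Hz bands between 10 and 100 Hz and the four 100 Hz bands
#' between 100 and 500 Hz (half-open intervals, see [spectral_bands()]).
#' The index arithmetic assumes 1 Hz resolution, i.e. a window whose
#' length equals the sampling rate.
#'
#' @param f One-sided amplitude spectrum from [amplitude_spectrum()].
#' @param resolution Spectral resolution in Hz; taken from `f`'s attribute
#'   when omitted. Must be 1 Hz.
#' @return Named numeric vector of 13 band averages.
#' @export
band_average_features <- function(f, resolution = NULL) {
  res <- spectrum_resolution(f, resolution)
  if (abs(res - 1) > 1e-9) {
    abort("band averages are defined for 1 Hz resolution (window length = fs)")
  }
  bands <- spectral_bands()
  out <- vapply(seq_len(nrow(bands)), function(b) {
    idx <- bands$low[b]:(bands$high[b] - 1)
    sum(f[idx]) / length(idx)
  }, numeric(1))
  names(out) <- bands$name
  out
}

#' Spectral-moment features
#'
#' Frequency centroid (FC), root-mean-square frequency (RMSF) and
#' root-variance frequency (RVF) of the one-sided amplitude spectrum,
#' treating `f` as a weight over its bin frequencies. The square roots in
#' RMSF and RVF follow the feature names; `literal_equations = TRUE`
#' returns the unrooted second moments instead.
#'
#' @inheritParams band_average_features
#' @param literal_equations If `TRUE`, RMSF and RVF are returned without
#'   the square root.
#' @return Named numeric vector `c(fc, rmsf, rvf)`.
#' @export
#' @examples
#' f <- amplitude_spectrum(sin(2 * pi * 50 * (0:999) / 1000), 1000)
#' spectral_shape_features(f)
spectral_shape_features <- function(f, resolution = NULL,
                                    literal_equations = FALSE) {
  res <- spectrum_resolution(f, resolution)
  s <- sum(f)
  if (s <= 0) abort("spectral moments are undefined for an all-zero spectrum")
  freqs <- seq_along(f) * res
  fc <- sum(f * freqs) / s
  msf <- sum(f * freqs^2) / s
  vf <- sum(f * (freqs - fc)^2) / s
  if (literal_equations) {
    c(fc = fc, rmsf = msf, rvf = vf)
  } else {
    c(fc = fc, rmsf = sqrt(msf), rvf = sqrt(vf))
  }
}

#' Time-domain features
#'
#' RMS amplitude, zero-crossing count (strict sign changes of adjacent
#' samples), mean absolute value, and standardized kurtosis (raw,
#' non-excess) and skewness using the population standard deviation
#' (divide by `L`). `literal_equations = TRUE` returns the mean square
#' instead of its root for the RMS feature.
#'
#' @param x Single-channel signal.
#' @param types Which of `c("rms", "zcr", "mav", "kurtosis", "skewness")`
#'   to compute (default all). Kurtosis and skewness error on a constant
#'   window (`sigma = 0`); the other features do not.
#' @param literal_equations If `TRUE`, RMS is returned unrooted.
#' @return Named numeric vector of the requested features.
#' @export
#' @examples
#' time_domain_features(rep(c(1, -1), 5))
time_domain_features <- function(x,
                                 types = c("rms", "zcr", "mav",
                                           "kurtosis", "skewness"),
                                 literal_equations = FALSE) {
  types <- match.arg(types, several.ok = TRUE)
  L <- length(x)
  if (L < 2) abort("time-domain features need at least 2 points")
  out <- numeric(0)
  if ("rms" %in% types) {
    ms <- mean(x^2)
    out <- c(out, rms = if (literal_equations) ms else sqrt(ms))
  }
  if ("zcr" %in% types) out <- c(out, zcr = sum(x[-L] * x[-1] < 0))
  if ("mav" %in% types) out <- c(out, mav = mean(abs(x)))
  if (any(c("kurtosis", "skewness") %in% types)) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (sigma == 0) {
      abort("kurtosis and skewness are undefined for a constant window (sigma = 0)")
    }
    z <- (x - mu) / sigma
    if ("kurtosis" %in% types) out <- c(out, kurtosis = mean(z^4))
    if ("skewness" %in% types) out <- c(out, skewness = mean(z^3))
  }
  out[intersect(c("rms", "zcr", "mav", "kurtosis", "skewness"), types)]
}

channel_features <- function(x, fs, types, literal_equations = FALSE) {
  band_names <- spectral_bands()$name
  shape_names <- c("fc", "rmsf", "rvf")
  time_names <- c("rms", "zcr", "mav", "kurtosis", "skewness")
  out <- numeric(0)
  if (any(types %in% c(band_names, shape_names))) {
    f <- amplitude_spectrum(x, fs)
    if (any(types %in% band_names)) out <- c(out, band_average_features(f))
    if (any(types %in% shape_names)) {
      out <- c(out, spectral_shape_features(f, literal_equations = literal_equations))
    }
  }
  if (any(types %in% time_names)) {
    out <- c(out, time_domain_features(x, types = intersect(time_names, types),
                                       literal_equations = literal_equations))
  }
  out[types]
}

#' Extract the per-window feature matrix
#'
#' Computes the selected feature types on the selected channels for every
#' non-rejected window and assembles the feature dataset: one row per
#' window, metadata columns (`trial`, `subject`, `session`, `taste`,
#' `window`) followed by feature columns named `ch<c>_<type>` in
#' channel-major order (channels ascending, the 21 types in canonical
#' order within each channel). The full configuration on 6 channels yields
#' 126 feature columns.
#'
#' @param windows Preprocessed window tibble ([preprocess_windows()]); a
#'   `rejected` column, when present, filters windows out.
#' @param channels Integer channel subset (default: all channels).
#' @param types Feature types as names or indices from
#'   [feature_types()] (default: all 21).
#' @param literal_equations If `TRUE`, RMS, RMSF and RVF are computed
#'   without their square roots.
#' @return A tibble (the feature dataset).
#' @export
extract_features <- function(windows, channels = NULL, types = NULL,
                             literal_equations = FALSE) {
  if ("rejected" %in% names(windows)) {
    windows <- filter(windows, !rejected)
  }
  if (nrow(windows) == 0) abort("no (unrejected) windows to extract features from")
  n_ch <- ncol(windows$data[[1]])
  channels <- channels %||% seq_len(n_ch)
  channels <- sort(as.integer(channels))
  if (length(channels) == 0) abort("channel set must not be empty")
  if (any(channels < 1 | channels > n_ch)) {
    abort(sprintf("channels must be in 1..%d", n_ch))
  }
  types <- if (is.null(types)) feature_types()$feature_type else match_feature_types(types)
  if (length(types) == 0) abort("feature-type set must not be empty")
  # canonical order within channel
  types <- feature_types()$feature_type[feature_types()$feature_type %in% types]

  fs <- windows$fs
  d <- length(channels) * length(types)
  mat <- vapply(seq_len(nrow(windows)), function(i) {
    x <- windows$data[[i]]
    unlist(lapply(channels, function(ch) {
      channel_features(x[, ch], fs[i], types, literal_equations)
    }), use.names = FALSE)
  }, numeric(d))
  mat <- if (d == 1) matrix(mat, ncol = 1) else t(mat)
  colnames(mat) <- as.vector(vapply(channels, function(ch) {
    paste0("ch", ch, "_", types)
  }, character(length(types))))

  meta <- select(windows, any_of(c("trial", "subject", "session", "taste", "window")))
  bind_cols(meta, as_tibble(mat))
}

#' @importFrom dplyr any_of
NULL

#' Identify and parse feature columns
#'
#' @param features A feature dataset from [extract_features()].
#' @return A tibble with columns `column`, `channel`, `feature_type` and
#'   `type_index`, in the dataset's column order.
#' @export
feature_columns <- function(features) {
  cols <- grep("^ch[0-9]+_", names(features), value = TRUE)
  ch <- as.integer(sub("^ch([0-9]+)_.*$", "\\1", cols))
  type <- sub("^ch[0-9]+_", "", cols)
  tibble(column = cols, channel = ch, feature_type = type,
         type_index = feature_types()$type_index[match(type, feature_types()$feature_type)])
}

#' Subset a feature dataset by type and channel
#'
#' Filters feature columns by feature type and/or channel while leaving
#' rows, labels and identifiers untouched. Subsetting twice equals a
#' single combined subset.
#'
#' @param features A feature dataset.
#' @param types Feature types (names or indices) to keep; `NULL` keeps all.
#' @param channels Channels to keep; `NULL` keeps all.
#' @return The filtered feature dataset.
#' @export
subset_features <- function(features, types = NULL, channels = NULL) {
  info <- feature_columns(features)
  keep <- rep(TRUE, nrow(info))
  if (!is.null(types)) {
    types <- match_feature_types(types)
    missing_t <- setdiff(types, info$feature_type)
    if (length(missing_t) > 0) {
      abort(sprintf("feature type(s) not in dataset: %s",
                    paste(missing_t, collapse = ", ")))
    }
    keep <- keep & info$feature_type %in% types
  }
  if (!is.null(channels)) {
    missing_c <- setdiff(channels, info$channel)
    if (length(missing_c) > 0) {
      abort(sprintf("channel(s) not in dataset: %s",
                    paste(missing_c, collapse = ", ")))
    }
    keep <- keep & info$channel %in% channels
  }
  meta <- setdiff(names(features), info$column)
  select(features, all_of(meta), all_of(info$column[keep]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
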