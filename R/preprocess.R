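#' Segment one trial into sliding windows
#'
#' Cuts a recording into overlapping windows of `window_s` seconds advanced
#' by `step_s` seconds. A window is emitted only if it fits entirely inside
#' the trial, so the number of windows is
#' `floor((n - L) / step) + 1` when `n >= L` and 0 otherwise.
#'
#' @param x Samples x channels matrix (a single channel may be a vector).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 1).
#' @param step_s Step between window starts in seconds (default 0.25).
#' @return A tibble with columns `window` (1-based index), `start`
#'   (0-based sample offset) and `data` (list of L x channels matrices).
#' @export
#' @examples
#' x <- matrix(rnorm(2000 * 2), ncol = 2)
#' nrow(segment_trial(x, fs = 1000))
segment_trial <- function(x, fs, window_s = 1, step_s = 0.25) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (window_s <= 0 || step_s <= 0) abort("window_s and step_s must be positive")
  L <- window_s * fs
  step <- step_s * fs
  if (abs(L - round(L)) > 1e-9 || abs(step - round(step)) > 1e-9) {
    abort("window_s and step_s must convert to integer point counts at this fs")
  }
  L <- as.integer(round(L)); step <- as.integer(round(step))
  n <- nrow(x)
  if (n < L) {
    return(tibble(window = integer(), start = integer(), data = list()))
  }
  starts <- seq(0L, n - L, by = step)
  tibble(
    window = seq_along(starts),
    start = starts,
    data = lapply(starts, function(s) x[(s + 1):(s + L), , drop = FALSE])
  )
}

#' Segment every trial of a study
#'
#' @param study Trial tibble as returned by [generate_study()] or
#'   [read_study()] (columns `trial`, `subject`, `session`, `taste`, `fs`,
#'   `data`).
#' @inheritParams segment_trial
#' @return A tibble with one row per window; trial metadata is copied
#'   verbatim onto each window.
#' @export
segment_windows <- function(study, window_s = 1, step_s = 0.25) {
  rows <- purrr::pmap(study, function(trial, subject, session, taste, fs, data, ...) {
    seg <- segment_trial(data, fs, window_s, step_s)
    if (nrow(seg) == 0) return(NULL)
    tibble(trial = trial, subject = subject, session = session,
           taste = taste, fs = fs,
           window = seg$window, start = seg$start, data = seg$data)
  })
  bind_rows(rows)
}

#' Remove a polynomial trend
#'
#' Subtracts, per channel, the least-squares polynomial of the given degree
#' fitted over the window's time axis. With the default degree 4 this
#' cancels quartic baseline drift from muscle-tension changes and device
#' zero drift.
#'
#' @param x Samples x channels matrix or a single-channel vector.
#' @param degree Polynomial order (default 4).
#' @return Detrended signal with the input's shape.
#' @export
remove_trend <- function(x, degree = 4) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  L <- nrow(x)
  if (L < degree + 2) {
    abort(sprintf("window of %d points is too short to fit a degree-%d trend",
                  L, degree))
  }
  basis <- cbind(1, stats::poly(seq_len(L), degree))
  res <- qr.resid(qr(basis), x)
  dimnames(res) <- dimnames(x)
  if (vec) drop(res) else res
}

butter_highpass <- function(order, cutoff, fs) {
  signal::butter(order, cutoff / (fs / 2), type = "high")
}

# Causal single-pass IIR with step-matched initial conditions: the filter
# state is initialized as if the first sample had been held forever, which
# suppresses the start-up transient on short windows.
filter_step_init <- function(b, a, x) {
  m <- length(b) - 1
  dc <- sum(b) / sum(a)
  signal::filter(b, a, x,
                 init.x = rep(x[1], m),
                 init.y = rep(x[1] * dc, m))
}

#' High-pass Butterworth filter
#'
#' Applies a causal order-`order` Butterworth high-pass once (single
#' forward pass), per channel. The steady-state magnitude response follows
#' `|H(f)|^2 = 1 / (1 + (cutoff/f)^(2 * order))`, i.e. -3.01 dB at the
#' cutoff. Defaults remove residual drift and motion energy below 10 Hz.
#'
#' @param x Samples x channels matrix or vector.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 10); must be below
#'   Nyquist.
#' @param order Filter order (default 4).
#' @return Filtered signal with the input's shape.
#' @export
highpass_filter <- function(x, fs, cutoff = 10, order = 4) {
  if (cutoff >= fs / 2) abort("cutoff must be below the Nyquist frequency")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  bf <- butter_highpass(order, cutoff, fs)
  out <- apply(x, 2, function(col) filter_step_init(bf$b, bf$a, col))
  dimnames(out) <- dimnames(x)
  if (vec) drop(out) else out
}

# One-sided amplitude spectrum used internally by the notch trigger.
one_sided_amplitude <- function(x) {
  L <- length(x)
  abs(fft(x))[2:(floor(L / 2) + 1)]
}

# Line-to-background amplitude ratio at one harmonic: spectrum peak within
# +-1 Hz of the harmonic against the background in a +-10 Hz neighborhood
# (the harmonic +-2 Hz excluded). The background is the larger of the two
# one-sided medians, which keeps the ratio near 1 when the harmonic sits
# on a spectral shelf (a steep power change between its two sides) while a
# genuine line still towers over both sides.
harmonic_ratio <- function(spec_amp, resolution, harmonic) {
  freqs <- seq_along(spec_amp) * resolution
  peak_sel <- freqs >= harmonic - 1 & freqs <= harmonic + 1
  left_sel <- freqs >= harmonic - 10 & freqs < harmonic - 2
  right_sel <- freqs > harmonic + 2 & freqs <= harmonic + 10
  if (!any(peak_sel) || !(any(left_sel) || any(right_sel))) return(0)
  sides <- c(if (any(left_sel)) median(spec_amp[left_sel]),
             if (any(right_sel)) median(spec_amp[right_sel]))
  bg <- max(sides)
  if (bg <= 0) return(Inf)
  max(spec_amp[peak_sel]) / bg
}

# |H|^2 of an RBJ second-order notch, evaluated on arbitrary frequencies.
notch_response_sq <- function(freqs, f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  w <- 2 * pi * freqs / fs
  E <- function(k) exp(-1i * k * w)
  num <- b[1] + b[2] * E(1) + b[3] * E(2)
  den <- 1 + a[2] * E(1) + a[3] * E(2)
  Mod(num / den)^2
}

#' Adaptive power-line notch
#'
#' For each harmonic of the power-line fundamental up to `max_harmonic`,
#' the window's one-sided amplitude spectrum is inspected: if the peak
#' within 1 Hz of the harmonic exceeds `trigger_ratio` times the
#' background amplitude of the surrounding 10 Hz neighborhood (the larger
#' of the two one-sided medians, the harmonic's immediate 2 Hz vicinity
#' excluded), a narrow second-order notch centred on that harmonic is
#' applied; otherwise the harmonic is left untouched.
#' When nothing triggers the signal passes through unchanged.
#'
#' The notch magnitude response is applied zero-phase in the frequency
#' domain (circular convolution), so an interference line that is
#' phase-continuous across the window is removed essentially completely
#' while energy outside the notch bandwidth (about `f0/Q` Hz) is
#' preserved.
#'
#' @param x Samples x channels matrix or vector.
#' @param fs Sampling rate in Hz.
#' @param fundamental Power-line fundamental in Hz (default 50).
#' @param max_harmonic Highest harmonic considered, in Hz (default 450).
#' @param trigger_ratio Peak-to-background ratio above which a harmonic is
#'   notched (default 4).
#' @param quality_factor Notch quality factor at the fundamental (default
#'   30, i.e. a 3 dB bandwidth of `fundamental/quality_factor` Hz). Higher
#'   harmonics use proportionally larger Q so that every notch in the comb
#'   has the same absolute bandwidth.
#' @return Filtered signal with the input's shape and an attribute
#'   `triggered`: a list (one element per channel) of the harmonic
#'   frequencies that were notched.
#' @export
adaptive_notch <- function(x, fs, fundamental = 50, max_harmonic = 450,
                           trigger_ratio = 4, quality_factor = 30) {
  if (fundamental >= fs / 2) abort("fundamental must be below Nyquist")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  L <- nrow(x)
  resolution <- fs / L
  harmonics <- seq(fundamental, min(max_harmonic, fs / 2 - resolution),
                   by = fundamental)
  freqs_full <- abs(c(0:(floor(L / 2)), -(ceiling(L / 2) - 1):-1)) * fs / L

  out <- x
  triggered <- vector("list", ncol(x))
  for (ch in seq_len(ncol(x))) {
    z <- fft(x[, ch])
    amp <- abs(z)[2:(floor(L / 2) + 1)]
    hit <- harmonics[vapply(harmonics, function(h) {
      harmonic_ratio(amp, resolution, h) > trigger_ratio
    }, logical(1))]
    triggered[[ch]] <- hit
    if (length(hit) > 0) {
      resp <- rep(1, L)
      for (h in hit) {
        # constant absolute bandwidth across the harmonic comb: Q scales
        # with the harmonic so every notch is fundamental/Q Hz wide
        resp <- resp * notch_response_sq(freqs_full, h, fs,
                                         quality_factor * h / fundamental)
      }
      out[, ch] <- Re(fft(z * resp, inverse = TRUE)) / L
    }
  }
  dimnames(out) <- dimnames(x)
  if (vec) out <- drop(out)
  attr(out, "triggered") <- triggered
  out
}

#' Flag windows with unremovable line interference
#'
#' After notch filtering, recomputes the line-to-background amplitude ratio
#' at every harmonic; the window is flagged for rejection if any ratio
#' still exceeds the threshold. Flagged windows are excluded from feature
#' extraction.
#'
#' @param x Notch-filtered samples x channels matrix or vector.
#' @inheritParams adaptive_notch
#' @param threshold Residual ratio above which the window is rejected
#'   (default 4).
#' @return Logical flag.
#' @export
reject_sample <- function(x, fs, fundamental = 50, max_harmonic = 450,
                          threshold = 4) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  L <- nrow(x)
  resolution <- fs / L
  harmonics <- seq(fundamental, min(max_harmonic, fs / 2 - resolution),
                   by = fundamental)
  for (ch in seq_len(ncol(x))) {
    amp <- one_sided_amplitude(x[, ch])
    for (h in harmonics) {
      if (harmonic_ratio(amp, resolution, h) > threshold) return(TRUE)
    }
  }
  FALSE
}

#' Clean segmented windows
#'
#' Runs the per-window cleaning chain on a window tibble: polynomial
#' detrend, causal high-pass Butterworth, adaptive power-line notch, and
#' rejection of windows whose residual interference the notch could not
#' remove. Shapes and metadata are never altered; rejection only sets a
#' flag.
#'
#' @param windows Window tibble from [segment_windows()].
#' @param detrend_degree Polynomial degree for detrending (default 4).
#' @param hp_cutoff,hp_order High-pass cutoff (Hz) and order.
#' @param fundamental,max_harmonic,trigger_ratio,quality_factor Notch
#'   parameters, see [adaptive_notch()].
#' @param reject_threshold Residual line ratio for rejection, see
#'   [reject_sample()].
#' @return The window tibble with cleaned `data`, a `notched` list-column
#'   of triggered harmonics, and a logical `rejected` column.
#' @export
preprocess_windows <- function(windows,
                               detrend_degree = 4,
                               hp_cutoff = 10, hp_order = 4,
                               fundamental = 50, max_harmonic = 450,
                               trigger_ratio = 4, quality_factor = 30,
                               reject_threshold = 4) {
  fs <- windows$fs
  cleaned <- vector("list", nrow(windows))
  notched <- vector("list", nrow(windows))
  rejected <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    y <- remove_trend(windows$data[[i]], degree = detrend_degree)
    y <- highpass_filter(y, fs[i], cutoff = hp_cutoff, order = hp_order)
    y <- adaptive_notch(y, fs[i], fundamental = fundamental,
                        max_harmonic = max_harmonic,
                        trigger_ratio = trigger_ratio,
                        quality_factor = quality_factor)
    notched[[i]] <- sort(unique(unlist(attr(y, "triggered"))))
    attr(y, "triggered") <- NULL
    rejected[i] <- reject_sample(y, fs[i], fundamental = fundamental,
                                 max_harmonic = max_harmonic,
                                 threshold = reject_threshold)
    cleaned[[i]] <- y
  }
  windows$data <- cleaned
  windows$notched <- notched
  windows$rejected <- rejected
  windows
}
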