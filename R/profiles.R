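#' Build a taste profile
#'
#' A taste profile encodes, for one taste class, the target amplitude of the
#' band-shaped sEMG component on every channel and spectral band. Gains
#' multiply the broadband noise floor of the study specification, so a gain
#' of zero silences a band entirely.
#'
#' @param taste One of [taste_levels()].
#' @param band_gain Numeric matrix, channels x 13 bands, non-negative.
#' @return An object of class `taste_profile`.
#' @export
taste_profile <- function(taste, band_gain) {
  taste <- as.character(as_taste(taste))
  band_gain <- as.matrix(band_gain)
  if (ncol(band_gain) != 13) {
    abort("band_gain must have exactly 13 columns (one per spectral band)")
  }
  if (any(band_gain < 0) || any(!is.finite(band_gain))) {
    abort("band gains must be finite and non-negative")
  }
  structure(list(taste = taste, band_gain = band_gain),
            class = "taste_profile")
}

#' Default taste profiles
#'
#' Profiles for all six classes on `n_channels` channels. All classes share
#' a common sEMG backbone with energy concentrated between 10 and 100 Hz;
#' the classes differ only in the 100-400 Hz bands of the contrast channels
#' (by default channels 3, 4 and 6, the single-ended electrodes over the
#' depressor anguli oris, depressor labii inferioris and masseter). The
#' contrast magnitudes order the classes as
#' Sour >> Salty ~ Bitter > Sweet ~ Umami > None, with distinct per-channel
#' patterns within each magnitude tier so that every class pair is
#' separable.
#'
#' @param n_channels Number of recording channels (default 6).
#' @param contrast_channels Channels whose 100-400 Hz bands carry the
#'   class contrast.
#' @return Named list of six [taste_profile()] objects.
#' @export
#' @examples
#' p <- default_taste_profiles()
#' p$Sour$band_gain[3, ]
default_taste_profiles <- function(n_channels = 6, contrast_channels = c(3, 4, 6)) {
  stopifnot(n_channels >= max(contrast_channels))
  base <- matrix(0, n_channels, 13)
  base[, 1:9] <- 1        # 10-100 Hz backbone: bulk of sEMG energy
  base[, 10:12] <- 0.3    # quiet 100-400 Hz floor
  base[, 13] <- 0.2       # 400-500 Hz tail

  # 100-400 Hz contrast patterns (bands 10-12) per contrast channel.
  contrast <- list(
    None   = rbind(c(0.30, 0.30, 0.30), c(0.30, 0.30, 0.30), c(0.30, 0.30, 0.30)),
    Sour   = rbind(c(3.00, 3.30, 3.60), c(3.20, 3.00, 3.40), c(2.80, 3.20, 3.00)),
    Sweet  = rbind(c(0.90, 0.70, 0.80), c(0.70, 0.90, 0.75), c(0.80, 0.75, 0.90)),
    Bitter = rbind(c(1.30, 1.60, 1.20), c(1.60, 1.20, 1.50), c(1.20, 1.50, 1.30)),
    Salty  = rbind(c(1.60, 1.30, 1.50), c(1.20, 1.60, 1.40), c(1.50, 1.20, 1.60)),
    Umami  = rbind(c(0.70, 0.90, 0.75), c(0.90, 0.75, 0.80), c(0.75, 0.90, 0.80))
  )

  profiles <- lapply(taste_levels(), function(tl) {
    g <- base
    g[contrast_channels, 10:12] <- contrast[[tl]][seq_along(contrast_channels), ]
    taste_profile(tl, g)
  })
  names(profiles) <- taste_levels()
  profiles
}

validate_profiles <- function(profiles, n_channels) {
  if (!is.list(profiles) || length(profiles) != 6) {
    abort("profiles must be a list of 6 taste_profile objects, one per taste")
  }
  lv <- sort(taste_levels())
  got <- sort(unname(vapply(profiles, function(p) p$taste, character(1))))
  if (!identical(lv, got)) {
    abort("profiles must cover each taste label exactly once")
  }
  for (p in profiles) {
    if (nrow(p$band_gain) != n_channels) {
      abort(sprintf("profile '%s' has %d channel rows but the study has %d channels",
                    p$taste, nrow(p$band_gain), n_channels))
    }
  }
  profiles[match(taste_levels(), vapply(profiles, `[[`, character(1), "taste"))]
}
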