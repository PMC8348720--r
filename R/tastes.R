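#' Taste class labels
#'
#' The six classes used throughout the package: a no-taste control plus the
#' five primary tastes. All label columns are factors with these levels, in
#' this order.
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' taste_levels()
taste_levels <- function() {
  c("None", "Sour", "Sweet", "Bitter", "Salty", "Umami")
}

as_taste <- function(x) {
  lv <- taste_levels()
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), lv)
  if (length(bad) > 0) {
    abort(sprintf("unknown taste label(s): %s (expected one of %s)",
                  paste(bad, collapse = ", "), paste(lv, collapse = ", ")))
  }
  factor(x, levels = lv)
}

#' Spectral band layout
#'
#' The 13 frequency bands used for the band-average features and for
#' band-shaped signal synthesis: nine 10 Hz-wide bands from 10 Hz to 100 Hz
#' and four 100 Hz-wide bands from 100 Hz to 500 Hz. Bands are half-open
#' `[low, high)`.
#'
#' @return A tibble with columns `band` (1-13), `low`, `high` (Hz) and
#'   `name` (the feature column suffix, e.g. `"band_10_20"`).
#' @export
#' @examples
#' spectral_bands()
spectral_bands <- function() {
  low <- c(seq(10, 90, by = 10), seq(100, 400, by = 100))
  high <- low + c(rep(10, 9), rep(100, 4))
  tibble(
    band = 1:13, low = low, high = high,
    name = sprintf("band_%d_%d", low, high)
  )
}

#' The 21 per-channel feature types
#'
#' Thirteen spectral band averages, three spectral-moment features
#' (frequency centroid FC, root-mean-square frequency RMSF, root-variance
#' frequency RVF) and five time-domain features (RMS, zero-crossing count
#' ZCR, mean absolute value MAV, kurtosis, skewness). The `type_index`
#' fixes the canonical ordering used for column naming and for
#' deterministic tie-breaking in importance rankings.
#'
#' @return A tibble with columns `type_index` (1-21), `feature_type` and
#'   `domain` (`"frequency"` or `"time"`).
#' @export
#' @examples
#' feature_types()
feature_types <- function() {
  tibble(
    type_index = 1:21,
    feature_type = c(spectral_bands()$name,
                     "fc", "rmsf", "rvf",
                     "rms", "zcr", "mav", "kurtosis", "skewness"),
    domain = c(rep("frequency", 16), rep("time", 5))
  )
}

match_feature_types <- function(types) {
  tab <- feature_types()
  if (is.numeric(types)) {
    bad <- setdiff(types, tab$type_index)
    if (length(bad) > 0) abort(sprintf("unknown feature type index: %s",
                                       paste(bad, collapse = ", ")))
    return(tab$feature_type[match(types, tab$type_index)])
  }
  bad <- setdiff(types, tab$feature_type)
  if (length(bad) > 0) abort(sprintf("unknown feature type: %s",
                                     paste(bad, collapse = ", ")))
  as.character(types)
}
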