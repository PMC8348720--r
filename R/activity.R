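#' Band amplitude sum
#'
#' Sum of the one-sided amplitude spectrum over a half-open frequency band
#' `[low, high)` Hz, the muscle-activity proxy S. With the default
#' 100-400 Hz band, `S = 100 * (band_100_200 + band_200_300 +
#' band_300_400)`, consistent with the band-average features' index
#' ranges.
#'
#' @param f One-sided amplitude spectrum at 1 Hz resolution.
#' @param low,high Band edges in Hz (defaults 100 and 400).
#' @param resolution Spectral resolution in Hz; taken from `f` when
#'   omitted. Must be 1 Hz.
#' @return The scalar S.
#' @export
band_sum <- function(f, low = 100, high = 400, resolution = NULL) {
  res <- spectrum_resolution(f, resolution)
  if (abs(res - 1) > 1e-9) abort("band_sum assumes 1 Hz resolution")
  if (low >= high) abort("low must be less than high")
  idx <- low:(high - 1)
  idx <- idx[idx >= 1 & idx <= length(f)]
  sum(f[idx])
}

#' Per-taste muscle-activity table
#'
#' For each taste class and each selected channel, averages the 100-400 Hz
#' amplitude sum S over all windows with that label. The default channels
#' 3, 4 and 6 read out the depressor anguli oris, depressor labii
#' inferioris and masseter through single-ended electrodes, whose
#' un-differenced signals reflect raw signal strength; 6 tastes x 3
#' channels gives the 18-entry activity table.
#'
#' @param features Feature dataset holding the 100-400 Hz band columns for
#'   the requested channels.
#' @param channels Channels to read out (default `c(3, 4, 6)`).
#' @return A `taste_activity` tibble with columns `taste`, `channel`, `S`.
#' @export
taste_activity <- function(features, channels = c(3, 4, 6)) {
  features$taste <- as_taste(features$taste)
  missing_t <- setdiff(taste_levels(), as.character(unique(features$taste)))
  if (length(missing_t) > 0) {
    abort(sprintf("no samples for taste class(es): %s",
                  paste(missing_t, collapse = ", ")))
  }
  need <- c("band_100_200", "band_200_300", "band_300_400")
  rows <- lapply(channels, function(ch) {
    cols <- paste0("ch", ch, "_", need)
    if (!all(cols %in% names(features))) {
      abort(sprintf("dataset lacks 100-400 Hz band features for channel %d", ch))
    }
    s <- 100 * rowSums(as.matrix(features[cols]))
    tibble(taste = features$taste, channel = ch, S = s)
  })
  out <- bind_rows(rows) |>
    group_by(taste, channel) |>
    summarise(S = mean(S), .groups = "drop") |>
    arrange(channel, taste)
  structure(out, class = c("taste_activity", class(out)))
}

#' Linear grayscale mapping
#'
#' Maps values linearly to integer grayscales over the whole table: the
#' smallest value to 0 (black) and the largest to 255 (white), rounding
#' half away from zero and clamping to `[0, 255]`. A constant input maps
#' to all zeros. The map is order-preserving.
#'
#' @param x Numeric vector or matrix.
#' @return Integer grayscales with the input's shape.
#' @export
#' @examples
#' grayscale_map(c(2, 4, 6))
grayscale_map <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) {
    g <- x * 0
  } else {
    g <- floor(255 * (x - rng[1]) / (rng[2] - rng[1]) + 0.5)
    g <- pmin(pmax(g, 0), 255)
  }
  storage.mode(g) <- "integer"
  g
}

#' Activity table with grayscale rendering
#'
#' Adds the grayscale column to a [taste_activity()] table. `invert =
#' TRUE` renders stronger activity as darker (255 minus the raw map), the
#' presentation used when shading muscles on a face diagram; the raw map
#' sends the largest S to 255.
#'
#' @param activity A `taste_activity` tibble.
#' @param invert Render stronger activity darker (default `FALSE`).
#' @return The activity tibble with an integer `gray` column.
#' @export
activity_grayscale <- function(activity, invert = FALSE) {
  g <- grayscale_map(activity$S)
  if (invert) g <- 255L - g
  mutate(activity, gray = g)
}
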