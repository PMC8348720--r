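Package: tastemg
Title: Primary Taste Recognition from Facial Surface Electromyography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for recognising primary taste sensations (none, sour,
    sweet, bitter, salty, umami) from multichannel facial surface
    electromyography (sEMG). Provides a synthetic study generator with
    band-shaped muscle activity, baseline drift and power-line interference;
    sliding-window segmentation with quartic detrending, high-pass Butterworth
    filtering and an adaptive 50 Hz harmonic notch; a 21-type per-channel
    feature extractor (spectral band averages, spectral moments and
    time-domain statistics); session-grouped random-forest cross-validation
    with Gini feature-type importance; exhaustive feature-type, channel and
    subject selection sweeps; and a band-energy muscle-activity grayscale map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
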