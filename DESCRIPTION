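Package: wagglemap
Title: Georeferencing Honeybee Waggle Dances into Foraging Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts decoded honeybee waggle-phase records (angle from
    vertical and frame-timed duration) into georeferenced foraging vector
    endpoints and search-area density maps. Includes solar-azimuth geometry
    (NOAA general solar-position equations), distance calibration against a
    feeder at known range, circular statistics for dance aggregation,
    kernel-density search-area mapping with a minimal enclosing circle
    summary, sampling/accuracy diagnostics for frame-quantized durations,
    and a synthetic dance simulator providing ground truth for end-to-end
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    jsonlite,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
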