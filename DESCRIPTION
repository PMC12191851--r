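Package: ecgtrace
Title: Digitize Scanned 12-Lead ECG Page Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers per-lead waveform signals from raster images of printed
    12-lead electrocardiogram (ECG) pages arranged as four lead columns by
    three lead rows plus a bottom rhythm strip. The pipeline crops and
    Gaussian-smooths the page, binarizes it with Otsu's method, locates the
    three lead-separator columns and four isoelectric baselines from
    projection histograms, and tracks each trace rightward from a seed point
    with windowed median search, gap carry-forward and jump validation.
    Extracted traces can be re-rendered to a binary page and scored against
    the original with a global structural similarity index (SSIM) and mean
    squared error (MSE). A seeded synthetic page generator with exact ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
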