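Package: ringclim
Title: Tree-Ring Chronologies, Climate Indices and Drought Resilience
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for dendroclimatological analysis of conifer
    stands: reads Tucson/RWL ring-width measurements, averages cores to
    per-tree series and species chronologies, removes the age trend with a
    frequency-calibrated cubic smoothing spline, and builds growth-index
    chronologies with Rbar and the expressed population signal (EPS).
    Derives heat-, water- and cold-related climate indices from daily
    meteorology (heat sums, hot/frost/ice/rain day counts, vapour pressure
    deficit, Thornthwaite potential evapotranspiration, the standardised
    precipitation-evapotranspiration index SPEI), flags climatic stress
    years by vegetation-period percentiles, correlates growth with monthly
    and seasonal climate through bootstrapped Pearson correlation
    functions, and quantifies per-tree drought resistance, recovery and
    resilience (Lloret indices) with non-parametric species comparisons.
    Includes a synthetic climate and forest generator with known ground
    truth for end-to-end validation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
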