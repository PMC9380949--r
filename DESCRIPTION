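Package: reefcurrents
Title: Sub-Surface Current and Temperature Regimes on Contrasting Coral Reef Morphologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising sub-surface hydrodynamic and thermal
    regimes on coral reefs from moored current-meter records. Provides
    quality control and deployment trimming for high-frequency (10-s)
    speed/direction/temperature series, scalar and magnitude-weighted vector
    averaging of current direction with the Yamartino directional standard
    deviation, hourly/daily/seasonal aggregation under a tropical four-season
    calendar, robust dispersion statistics (quartiles, IQR, MAD) with
    pairwise permutation tests between reef types, random-intercept
    group-comparison models with Tukey-adjusted marginal-mean contrasts,
    current-rose and polar-temperature summary tables, and in-situ versus
    satellite sea-surface-temperature offset analysis. A synthetic
    current-meter data generator with reef-archetype presets (nearshore
    emergent, offshore emergent, submerged pinnacle) makes the full pipeline
    runnable and testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    lubridate,
    purrr,
    readr,
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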