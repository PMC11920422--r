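Package: bioalbedo
Title: Bioalbedo Analysis of Glacier-Algae Blooms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the darkening effect of snow and glacier
    algae on ice surfaces. Processes field spectrometer scans into
    hemispherical directional reflectance factors (HDRF), computes the
    instantaneous radiative forcing (IRF) of algal patches against a clean
    reference surface, fits and applies the log-linear relationship between
    IRF and cell density, classifies multispectral imagery into algal
    presence/absence by the continuum-scaled chlorophyll-a band depth and
    derives bloom extent, and runs a five-minute energy-balance melt model
    (shortwave plus sensible heat) with and without algal forcing to estimate
    the biological contribution to surface melt. A seeded synthetic-data
    module generates parametric snow and weathering-crust spectra, density-IRF
    datasets, diurnal weather series and labelled multiband scenes for testing
    and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
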