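Package: nirtherm
Title: Solar-Weighted Reflectivity and Thermal Statistics for
    Near-Infrared Reflectance Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the thermal consequences of near-infrared
    (NIR) reflectance in small ectotherms and physical models. Reads,
    calibrates and splices reflectance spectra from paired UV-Vis and NIR
    spectrometers, computes solar-irradiance-weighted reflectivity over
    arbitrary wavelength bands with exponential-decline or linear spectral
    extensions, extracts heating rates and end-of-phase temperatures from
    laboratory heating/cooling traces under a programmable illumination
    schedule, and fits the field statistics for paired thermal deployments:
    surface-versus-leaf temperature deltas, daily 95th-percentile internal
    temperatures, and paired temperature-difference series with first-order
    autoregressive residuals, all summarised with Wald chi-square tests and
    maximum-likelihood group estimates. A synthetic-data module generates
    reflectance spectra, chamber heating traces and diurnal field series with
    the statistical structure the analyses assume, so the full pipeline is
    testable without access to raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    nlme,
    car,
    emmeans,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
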