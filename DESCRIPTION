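Package: trbs
Title: Simulation and Depth-Resolved Analysis of Time-Resolved Brillouin
    Scattering Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physics-based simulator and analysis pipeline for time-resolved
    Brillouin scattering (TRBS) time-of-flight signals from layered
    viscoelastic specimens, as acquired by fibre-tip phononic microscopes.
    Generates synthetic pump-probe reflectivity traces from layered phantoms
    with known ground truth (including a nematode cuticle stack and
    cell-on-dish step phantoms), and converts such traces into depth-resolved
    Brillouin frequency shifts via complex-Morlet continuous wavelet
    transforms and ridge extraction, surface profilometry from
    attenuation-compensated amplitude roll-off, longitudinal modulus
    estimates, and Gaussian layer-thickness fits.
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
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
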