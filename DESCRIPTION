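Package: betaburn
Title: Radiation-Damage Characterization for Macromolecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans and analyses burn/collect experiments that measure the
    sensitivity of macromolecular crystals to X-ray radiation damage. Computes
    absorbed dose rates from beam flux, photon energy, beam size and crystal
    chemical composition; generates interleaved data-collection/irradiation
    protocols (11 narrow-wedge collections with burn exposures in between);
    simulates Wilson-distributed diffraction intensities decaying with dose;
    estimates per-wedge relative scales and isotropic B-factors by iterative
    weighted shell scaling; and fits the B-factor decay rate beta (A^2/MGy)
    versus absorbed dose, with composition-corrected sensitivities and
    per-position summaries.
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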