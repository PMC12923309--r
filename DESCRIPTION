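Package: lightheat
Title: Layered-Tissue Photon Monte Carlo and Photothermal Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted photon-packet Monte Carlo transport through layered
    biological tissue (hop-drop-spin with Henyey-Greenstein scattering,
    Fresnel boundaries and Russian roulette), convolution of the
    point-source impulse response with a finite Gaussian beam, and the
    downstream thermal analyses used in near-infrared photothermal therapy
    studies: photothermal conversion-efficiency estimation from
    heating/cooling traces, CEM43 thermal dose, contrast-enhancement
    ratios and a photoacoustic signal proxy. Includes models of
    indocyanine-green monomer and J-aggregate absorption spectra,
    dose-based mixing of contrast-agent optical properties into a tumor
    layer, and seeded synthetic-data generators for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
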