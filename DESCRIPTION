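Package: nirmc
Title: Monte Carlo Photon Transport for Second Near-Infrared Window
    Neuroimaging in a Layered Mouse Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Weighted-photon Monte Carlo simulation of light transport
    through a four-layer model of the hairless mouse head (scalp skin,
    skull, cerebrospinal fluid, cortex).  Simulates 785 nm excitation and
    1100 nm quantum-dot emission with Henyey-Greenstein scattering,
    Fresnel boundary interaction, Russian-roulette termination and (r, z)
    fluence scoring; couples excitation dose at depth to isotropic
    fluorescence re-emission with inherited weight; and applies
    numerical-aperture-limited collection and the Berek depth-of-field
    equation to evaluate the optimal focal plane for non-invasive
    cerebrovascular imaging in the second near-infrared window.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
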