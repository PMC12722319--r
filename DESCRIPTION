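Package: polyrisk
Title: Crystal Energy Landscapes, Powder-Pattern Matching and Polymorph Risk
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for retrospective solid-form risk assessment of molecular
    crystals: a CIF reader/writer with symmetry expansion and crystallographic
    density, kinematic powder X-ray diffraction simulation (structure factors,
    Lorentz-polarization, pseudo-Voigt profiles), weighted cross-correlation
    (de Gelder-type) pattern similarity for identifying predicted structures
    against an experimental pattern, an isolated-site Boltzmann model for
    configurational disorder corrections, assembly of free-energy-vs-density
    crystal landscapes with uniform vibrational shifts and two-tier error
    bars, and conversion of the landscape into stability probabilities,
    solubility-ratio estimates and a severity classification. A synthetic-data
    module generates toy structures, noisy powder patterns, candidate
    landscapes with ground truth, and disorder ensembles for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
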