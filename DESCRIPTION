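Package: efmr
Title: Embedded Fragment Method for Molecular Clusters in Magnetic Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Energies, electron densities and mean interaction energies of
    noncovalently bound molecular clusters via a second-order many-body
    expansion with a self-consistently optimized point-charge dipole
    embedding field, short-range erf attenuation of the embedding potential,
    and an embedded counterpoise correction for basis-set superposition
    error. Ships a Gaussian-basis self-consistent-field engine (real
    restricted Hartree-Fock; complex general Hartree-Fock with common
    gauge-origin or London-atomic-orbital treatments of a uniform external
    magnetic field) together with MP2 correlation, a McMurchie-Davidson
    molecular-integral backend with complex Boys functions, Gaussian94 basis
    input, XYZ cluster input/output and a synthetic water-cluster generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
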