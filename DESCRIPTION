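Package: microdsb
Title: Microdosimetry and Prompt DNA Double-Strand-Break Yields for kV and MV X-Ray Beams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale computation chain for comparing X-ray beam
    qualities (40 kVp, 220 kVp and 4 MV) irradiating an endothelial-cell
    monolayer. Builds filtered bremsstrahlung photon spectra, partitions
    photon interactions in liquid water, samples and transports secondary
    electrons with a table-driven track-structure model, scores specific
    energy across a population of elliptical-cylinder cell-nucleus
    phantoms (f(z;D), microdosimetric spread, pair-cumulation dose
    doubling, compound-Poisson oracle), maps energy depositions onto a
    statistical 6 Gbp hetero/euchromatin genome model, simulates water
    radiolysis with Brownian-dynamics reaction kinetics, and clusters
    backbone strand breaks into simple and complex double-strand breaks to
    obtain DSB/Gy/Gbp yields and relative biological effectiveness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
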