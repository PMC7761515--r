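Package: lfstretch
Title: Stretching Ensembles and Legendre-Fenchel Free-Energy Transforms for
    Short Polymers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Langevin-dynamics sampling of coarse-grained bead-spring chains
    (Morse bonds, harmonic bends, cosine-series torsions) in the isometric
    (fixed end-to-end distance) and isotensional (constant force) ensembles,
    thermodynamic integration of force-elongation curves into Helmholtz and
    Gibbs stretching energies, and free-energy transforms relating the two:
    the exact beta-weighted integral transform, the Legendre and
    Legendre-Fenchel transforms, the biconjugate (convex envelope), and
    diagnostics for the kinks that signal ensemble inequivalence in small
    chains.  Brute-force quadrature references for dimers and trimers and a
    parametric non-convex toy free-energy generator make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
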