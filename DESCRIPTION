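Package: pincerflex
Title: Integrative Conformational Analysis of Multi-Domain Pincer Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying large inter-domain motions of
    ultra-multimodular proteins by integrative structure determination:
    domain-based collective variables (inter-domain center-of-mass distance
    and four-domain torsion), elastic-network normal mode analysis,
    coarse-grained Langevin and metadynamics sampling with free-energy-surface
    reconstruction and microstate binning, SAXS profile computation (Debye
    sum, Guinier, pair-distance distribution, Porod-Debye) and multi-state
    ensemble fitting with non-negative population weights, plus a synthetic
    pincer-protein generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    pracma,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
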