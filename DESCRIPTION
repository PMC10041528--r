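Package: micellemotifs
Title: Unsupervised Reconstruction of Molecular Motifs in Surfactant Micelles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-driven reconstruction of the structural environments
    ("molecular motifs") that emerge on mono- and bicomponent surfactant
    micelles and of their exchange dynamics. Ships a minimalistic
    implicit-solvent coarse-grained Langevin simulator of five-bead
    amphiphiles, SOAP (Smooth Overlap of Atomic Positions) power-spectrum
    descriptors centred on surfactant head groups, PCA dimensionality
    reduction with TwoNN intrinsic-dimension estimation, PAMM-style
    density-peak clustering (farthest-point-sampled grid, anisotropic
    kernel density estimation, quick-shift mode assignment), and
    interconversion diagrams (cluster populations, conditional transition
    probabilities, species compositions) together with structural
    observables (radial distribution functions, head contacts, gyration
    radius). Trajectories can be generated internally or ingested from
    GRO/XYZ files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
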