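Package: phceff
Title: Supply Efficiency Dynamics of Primary Healthcare Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures and analyses the supply efficiency of primary medical
    and health services across regions and years. Implements the non-oriented
    slack-based-measure (SBM) data envelopment model with super-efficiency
    scoring under variable or constant returns to scale, Gaussian kernel
    density estimation of the cross-sectional efficiency distribution with
    peak-shape descriptors, exact Fisher-Jenks natural-breaks state
    classification, traditional and spatial-lag-conditioned Markov transition
    matrices on a contiguity graph, and limiting-distribution trend
    prediction by power iteration. Ships a reference panel of super-efficiency
    SBM scores for 20 central and western Chinese provinces (2010-2019) with
    a first-order contiguity map, plus seeded synthetic generators (DEA
    panels with a constructed frontier, state panels evolving under known
    transition kernels, random contiguity graphs) that give every pipeline
    stage a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
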