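Package: qfuzzy
Title: Quantum-Behaved Binary Particle Swarm Feature Selection with
    Fuzzy k-NN for Single-Cell Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for Pap-smear single-cell image
    classification. Extracts 17 morphometric, intensity and texture
    features (54 vector entries, including rotation-invariant LBP
    histogram-Fourier texture and GLCM homogeneity) from segmented
    cell images, then selects feature-vector entries with a binary
    quantum-behaved particle swarm optimiser (QPSO) whose fitness is
    the cross-validated macro-F1 of a fuzzy k-nearest-neighbour
    classifier. A standard binary PSO baseline, an all-features
    baseline, precision/recall/F1 and Cohen's kappa evaluation, and a
    synthetic segmented-cell generator emulating the seven Herlev
    classes are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
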