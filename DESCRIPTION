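Package: shapecode
Title: Neural Coding of 3D Shape for Grasping: Superquadrics, Depth
    Features, and Isomap Shape Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the transformation of 3D shape information along the
    dorsal visual pathway from the caudal intraparietal area (CIP) to
    visual-dominant neurons in the anterior intraparietal area (AIP).
    Provides a superquadric shape family with symmetry-aware
    canonicalization and database sampling, observer-centered depth-map
    rendering by ray casting on a foveated angular grid, CIP-like
    depth-derivative feature extraction, cosine-tuned leaky
    integrate-and-fire (LIF) neuron models with multistart least-squares
    tuning-curve fitting, a nonlinear dendritic-branch model, Neural
    Engineering Framework decoding and synaptic weight composition, Isomap
    embedding of depth-derivative features with out-of-sample extension,
    and feedforward network regression from depth features to shape
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
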