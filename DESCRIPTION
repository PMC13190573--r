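Package: circuitome
Title: Circuit Architecture Analysis of Region-Intrinsic Neurons in Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying region-intrinsic neurons in synapse-level
    connectome datasets and characterising their circuit architecture.
    Implements completeness thresholding from synapse-count distributions,
    region-fraction based intrinsic-neuron detection with type completion,
    Shannon-entropy diversity tests against labeled-line, mixed, and shuffled
    null models, a directed triad motif census with network significance
    profiles, Bray-Curtis/Ward and UMAP/HDBSCAN connectivity atlases,
    multi-layer relative-connectivity tracing of sensory modalities,
    NBLAST-style morphological similarity with ensemble identification and
    cross-dataset matching, and subcellular synaptic-topology analysis on
    neuron skeletons (geodesic synapse distributions, axon-initial-segment
    detection, force-directed and ranked dendrograms). Ships a seeded
    synthetic-connectome generator with planted ground truth so every stage
    is testable without connectome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    uwot,
    RANN,
    reticulate,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
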