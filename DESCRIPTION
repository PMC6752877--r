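Package: midnet
Title: Functional Connectivity and Topology of Cultured Neuronal Networks from Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-neuron-resolution calcium-imaging
    recordings of cultured neuronal networks: delta-F/F normalisation and
    integrated-activity summaries, Spearman rank functional-connectivity
    matrices, absolute and proportional (top-fraction) thresholding,
    weighted undirected network topology (density, Onnela clustering
    coefficient, Louvain modularity Q, strength assortativity), and
    baseline-versus-treatment comparison statistics (unity-line deviations
    with moment, Kolmogorov-Smirnov and Wilcoxon summaries; linear trends
    across days in vitro). Includes a parameterised spiking/GCaMP6f
    simulator of a mixed dopaminergic/GABAergic culture with D2-receptor
    drug modulation, culture-age connectivity decay, planted modular and
    assortative structure, and synthetic movie rendering, so every pipeline
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    e1071
Config/testthat/edition: 3
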