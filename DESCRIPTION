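Package: octaquant
Title: Simulation and Quantification of OCT Angiography En-Face Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how lateral optical resolution affects optical
    coherence tomography angiography (OCTA) metrics. Generates synthetic
    parafoveal vascular networks with a foveal avascular zone, renders them
    into en-face angiograms under configurable beam/sampling geometries
    (Gaussian point-spread function, grid sampling, speckle and background
    noise, repeated acquisitions), and quantifies the images with a Frangi
    vesselness enhancement, noise-based binarization, topology-preserving
    skeletonization, perfusion and vessel density on a fovea-centered
    annulus, and foveal avascular zone morphometry. Includes phase-correlation
    registration and averaging of repeated scans, acquisition quality gating,
    exact Wilcoxon signed-rank tests, single-measure absolute-agreement
    intraclass correlation, and a paired-cohort study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    deldir,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
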