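Package: angiotomo
Title: Propagation-Based Phase-Contrast Tomography Simulation and 3D
    Vascular Network Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis chain for propagation-based (in-line)
    X-ray phase-contrast tomography of vascular networks.  Generates
    synthetic branching-vessel phantoms with ground-truth morphometry,
    simulates parallel-beam acquisition with Fresnel free-space propagation,
    flat/dark fields and Poisson counting noise, performs single-distance
    TIE-HOM (homogeneous-object transport-of-intensity) phase retrieval,
    filtered back-projection reconstruction, FFT phase-correlation stitching
    of vertically overlapping half-scans, grey-level vessel segmentation,
    topology-preserving 3D skeletonization with distance-map diameters,
    graph-based network morphometry (bifurcations, segments, lengths,
    vessel volume fraction, diameter spectrum), and virtual micro-endoscopy
    (centerline path planning, camera fly-through poses, surface meshing).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
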