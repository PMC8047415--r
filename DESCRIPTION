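Package: atriavuln
Title: Arrhythmia Vulnerability Assessment on Synthetic Atrial Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale workbench for in-silico atrial arrhythmia
    vulnerability assessment. Provides a monodomain reaction-diffusion
    solver on synthetic 1D strands and 2D sheets with heterogeneous
    conductivity and percolation-type fibrosis, the Courtemanche-1998
    human atrial ionic model plus remodeling presets and a fast
    phenomenological test model, three arrhythmia induction protocols
    (rapid pacing with per-beat or end-of-train checking, pacing at the
    end of the effective refractory period with run-time binary-search
    ERP probing, and phase-singularity-distribution initialization via
    an eikonal activation map), and phase-based analysis of induced
    episodes (phase singularity detection, tracking, and episode
    classification into multiple-wavefront, flutter, and long-living
    phase-singularity classes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
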