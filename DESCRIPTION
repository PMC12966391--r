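Package: mwconn
Title: Microstructure-Weighted Structural Connectomes and Their Reproducibility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale emulation of a microstructure-weighted connectome
    study. Simulates multi-shell diffusion-weighted MRI signals from ball,
    stick, zeppelin and Bingham-dispersed compartment models, fits the
    diffusion tensor and the Bingham-NODDI multi-compartment model per voxel,
    builds structural connectomes whose edges carry SIFT2-weighted means of
    per-streamline median microstructure values (tractometry), extracts
    weighted graph metrics (density, global efficiency, nodal strength,
    clustering coefficient, Louvain modularity), and runs the test-retest
    reliability battery (coefficient of variation, Bland-Altman bias and
    limits of agreement, ICC(2,1)) on two-site per-subject network metrics.
    Includes synthetic generators for crossing-fibre phantoms, two-site
    replicate data and tractogram/parcellation fixtures with analytically
    known connectome ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    minpack.lm,
    pracma,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
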