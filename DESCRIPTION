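Package: colonyvox
Title: Spatial Physiology Quantification for Colony-Biofilm Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies spatial physiology in bacterial colony biofilms from
    multi-channel 3D confocal stacks: per-slice gradient-threshold
    segmentation with convex-hull biovolume, anisotropy-aware Euclidean
    distance to the air-facing colony surface, fluorescence-versus-depth
    profiles in axial-cylinder, basal-plane and isotropic-shell geometries,
    dead-cell fractions from dual-channel colocalization restricted to the
    oxic shell, ratiometric unstable/stable reporter growth readouts, colony
    height-radius morphometry with a bulge (slope-at-height) metric, and
    strain competition ring ratios. Includes a calibrated synthetic-colony
    generator with exact ground truth so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    xml2,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
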