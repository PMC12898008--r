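Package: osteomargin
Title: Patient-Specific Dangerous-Region Generation for Bone Tumor
    Resection Planning
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates patient-specific "dangerous regions" for
    computer-assisted bone tumor resection: the tumor plus all surrounding
    tissue within a prescribed safety margin, computed on anisotropic CT
    voxel grids by an exact anisotropic Euclidean distance transform with a
    coarse/fine two-resolution refinement, and reconstructed into a closed
    triangulated surface for osteotomy-plane clearance checking. Includes
    analytic phantoms for validation and a cohort-statistics module
    (descriptive statistics, MSTS functional scores, Kaplan-Meier survival)
    for the accompanying retrospective pelvic-tumor cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    survival,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
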