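Package: fibroquant
Title: Dual-Echo UTE MRI Lesion Decomposition and Collagen-PET
    Quantification for Bleomycin Lung-Injury Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for preclinical lung-fibrosis imaging in
    the rat bleomycin model. Separates MRI-visible lung lesions into an
    inflammatory fluid ("edema") compartment and a fibrosis-associated
    ("tissue") compartment by histogram thresholding of paired
    ultra-short-echo-time (UTE) volumes acquired at two echo times, with
    vessel subtraction and ROI set difference. Transfers the MRI-derived
    regions onto the PET grid and quantifies collagen-tracer uptake as
    percent injected dose (%ID) per compartment, including distance-ring
    profiles around lesion borders and Cu-64 decay correction. Includes a
    seeded digital rat-thorax phantom generator (label maps, dual-echo
    simulation with Rician noise, PET simulation with Poisson counting)
    for end-to-end validation against known ground truth, a delta-delta-Ct
    qPCR quantifier with dual reference genes, and group-comparison
    reporting with tiered significance symbols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
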