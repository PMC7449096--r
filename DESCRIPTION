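Package: nutct
Title: Walnut Morphometric Phenotyping from X-ray CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 3D image-analysis pipeline for non-destructive phenotyping of
    in-shell walnuts from reconstructed X-ray computed tomography volumes.
    Batches of nuts scanned in a low-attenuation foam holder are denoised and
    thresholded into a foreground mask, individualized by 3D connected-component
    labelling (with an optional distance-transform watershed splitter for
    touching nuts), and each nut is segmented into shell, kernel and enclosed
    empty space by histogram clustering, multi-level thresholding and
    marker-based watershed. Fourteen morphological descriptors are quantified
    per nut (principal-axis lengths, compartment volumes, mesh-based surface
    area, sphericity, rugosity, the VA3D shape factor, the 3D Feret shape
    index, inscribed-sphere shell thickness and the kernel filling ratio),
    with shell-integrity quality control that excludes damaged nuts. Includes
    a synthetic phantom generator with closed-form and brute-force ground
    truth for end-to-end validation, plus dataset-level descriptive
    statistics, Pearson correlation and PCA utilities for trait tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
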