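Package: ocusurf
Title: RANSAC Ocular Surface Estimation and Layered Vessel Analysis for
    Photoacoustic Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing 3D optical-resolution photoacoustic
    microscopy (OR-PAM) volumes of the anterior eye. Estimates the
    eyeball's center position and half-diameter from binarized vascular
    signal with an iterative random-sample-consensus (RANSAC) search,
    reconstructs surface-based depth-encoded images, isolates
    supra-surface (limbal, corneal neovascular) and on-surface
    (iris, choroidal/retinal) vessel layers by radial banding, and
    quantifies corneal neovascularization area with a spherical-slope
    cosine correction. Includes a spherical-shell phantom generator with
    known ground truth, an A-line preprocessing chain (band-pass,
    Hilbert envelope, downsizing, binarization), an ANSI
    maximum-permissible-exposure laser-safety calculator, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
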