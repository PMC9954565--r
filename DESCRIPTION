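Package: pcdscreen
Title: Transport Physics and Experiment Logic for Pixelated Chemical
    Display Drug Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale models of an open-space microfluidic drug
    screening platform in which a pixelated chemical display (PCD)
    projects isolated reagent "pixels" onto a microwell array holding 3D
    tumour models.  Provides the device geometry and pixel/well layouts;
    a depth-averaged (Hele-Shaw) source/sink flow model with wall shear
    stress, pixel footprints and crosstalk; axisymmetric reagent
    transport into a well and tissue with time-to-steady-state and dye
    accumulation; a static-culture oxygen/glucose viability model with
    Michaelis-Menten uptake; treatment-schedule arithmetic with
    transition-time-aware effective exposures; fluorescence and nuclear
    translocation quantification with nonparametric group comparison;
    and seeded generators of synthetic micrographs and mask pairs with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
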