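Package: her2forecast
Title: Imaging-Informed Forecasting of Breast Tumor Response to Neoadjuvant
    and HER2-Targeted Therapy
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A mechanically coupled reaction-diffusion framework for
    forecasting the response of HER2-positive breast tumors to neoadjuvant
    chemotherapy and HER2-targeted antibody therapy from longitudinal
    multi-modal imaging. Voxelwise tumor cellularity is estimated from
    diffusion-weighted MRI via the apparent diffusion coefficient, drug
    delivery surrogates are derived from dynamic contrast-enhanced MRI
    (normalized area under the enhancement curve) and radiolabeled-antibody
    PET uptake, tissue mechanics damp tumor cell diffusion through the von
    Mises stress of a linear-elastic equilibrium, and the model is calibrated
    between two imaging visits by bounded Levenberg-Marquardt least squares
    (global drug/diffusion parameters plus a voxelwise proliferation map)
    before being run forward to the time of surgery. Includes a virtual
    patient generator so that the full pipeline is testable without
    clinical data, minimal NIfTI-1 input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
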