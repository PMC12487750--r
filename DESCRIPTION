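Package: petvalid
Title: PET Scanner Calibration and Recovery-Coefficient Validation for
    Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the standardized quantitative validation of PET/CT
    scanners used in multicentre clinical trials. Implements phantom fill
    planning and accounting with radionuclide decay correction, a synthetic
    phantom-scan simulator with a Gaussian point-spread partial-volume model
    and injectable calibration bias, slice-wise calibration-bias analysis of
    uniform phantoms, contrast-recovery-coefficient (CRC) and recovery-
    coefficient (RC) curve measurement from sphere phantoms (centroid VOI
    placement, exact-size sphere VOI, maximum-voxel and 1-cm3 peak metrics),
    and an acceptance engine encoding tiered calibration tolerances,
    harmonized per-sphere CRC limits, validity windows and revalidation
    triggers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    openssl
Config/testthat/edition: 3
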