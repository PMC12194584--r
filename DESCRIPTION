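Package: acrcnr
Title: Automatic Contrast-to-Noise Ratio Measurement for the ACR CT Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-based automatic measurement of the contrast-to-noise
    ratio (CNR) on low-contrast-module images of the ACR CT accreditation
    phantom. The largest low-contrast object (25 mm cylinder) is localized by
    rotating a circular region of interest at 55 mm from the phantom centroid
    in 2-degree steps and taking the angle of maximum mean CT number; CNR is
    the mean CT-number difference between the object ROI and a central
    background ROI divided by the background standard deviation. Includes
    calibrated Hounsfield-unit image input from uncompressed single-frame CT
    DICOM files, a synthetic phantom-slice generator with known ground truth
    for validation, batch QC reporting with automatic-versus-manual comparison
    (percent difference, Mann-Whitney U test), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
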