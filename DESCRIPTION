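Package: pcquant
Title: Quantification of Protocell Uptake, Transport and Tumor Burden from
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for microcapsule ("protocell")
    delivery experiments in zebrafish: calibrated multi-channel TIFF stacks,
    detection by adjustable Otsu/mean thresholding with connected-components
    labeling and watershed splitting, leukocyte containment and colocalization
    scoring, directionally gated particle tracking with instantaneous
    velocities, pigmentation and stained-area fractions, tumor growth curves
    and serial-section (Cavalieri) volume reconstruction. Includes a
    deterministic synthetic-microscopy generator that plants known ground
    truth (containment fractions, flow velocities, section volumes, dark-pixel
    fractions) so every stage is verifiable without original imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
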