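Package: petthresh
Title: Adaptive SUV Threshold Prediction for PET Tumour Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Threshold-based segmentation of hypermetabolic tumours in PET
    standardized-uptake-value (SUV) volumes. For every axial slice, six
    uptake-distribution attributes (area and mean SUV inside the 0.10, 0.15
    and 0.20 x SUV70 contours) are computed and a kernel support-vector
    regressor is trained to predict the SUV threshold whose superlevel-set
    contour best matches a reference gross tumour volume. Includes reference
    label construction by best-Jaccard threshold search, a contrast-oriented
    baseline (mean background + 0.15 x SUV70), repeated random-split
    evaluation with Jaccard and Pearson metrics, NIfTI volume input/output,
    and a synthetic thorax phantom generator with gated and free-breathing
    (respiratory motion averaged) acquisition modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
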