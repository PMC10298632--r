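Package: knetmri
Title: Multi-Sequence Knee MRI Injury Classification with Feature-Fusion CNNs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for binary classification of knee injuries
    (general abnormality, medial meniscus tear, bone marrow edema) from
    multi-sequence knee MRI exams. Implements DICOM series reading and
    writing, intensity windowing and training-set z-normalization, feature
    fusion of the original slice with local binary pattern (LBP) and Haar
    discrete wavelet transform (DWT) representations, a slice-aggregating
    convolutional network (KNet) with softmax attention pooling and its
    multi-stream extension (MS-KNet), class-weighted binary cross-entropy
    training, threshold-0.5 evaluation (accuracy, sensitivity, specificity),
    and an ablation harness over input-sequence combinations. A synthetic
    multi-sequence knee-phantom generator with planted lesions makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
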