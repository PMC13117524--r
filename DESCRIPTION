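Package: morphfer
Title: Morphological Residual Features for Facial Expression Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grayscale mathematical morphology (flat dilation, erosion, opening,
    closing) and the four directional residual transforms (external/internal
    gradients and white/black top-hats) used as structural input channels for
    convolutional facial-expression classifiers. Provides the morphology-CNN
    hybrid architectures (MCNN1, the six three-channel MCNN2 variants, a
    dense-only morphological-network baseline and backbone adapters), a
    subject-independent k-fold and leave-one-dataset-out evaluation protocol
    with training-only augmentation, macro precision/recall/F1 metrics, and a
    deterministic parametric generator of multi-subject, multi-source synthetic
    face images so every pipeline stage is testable without licensed corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, png, jsonlite
Suggests: testthat (>= 3.0.0), jpeg
Config/testthat/edition: 3
RoxygenNote: 7.3.3
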