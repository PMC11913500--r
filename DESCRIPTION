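Package: dermrestore
Title: Dermoscopic Image Restoration: Hair Removal, Denoising, and a
    Classification Harness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Restoration of dermoscopic skin-lesion images corrupted by hair
    strands and sensor noise, and tools to measure the effect of restoration
    on downstream lesion classification. Implements blackhat-morphology hair
    segmentation followed by fast-marching (TELEA-style) inpainting, and
    non-local means denoising with a CIELAB luminance/chroma split. Ships a
    seeded synthetic corpus generator (lesion phantoms, procedural hairs,
    Gaussian noise) so every stage is testable without external data, plus a
    backbone-agnostic transfer-learning harness (frozen feature extractor,
    trainable softmax head) reporting training/validation accuracy and loss.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
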