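Package: protoseg
Title: Prototype-Based Few-Shot Image Segmentation with Adversarial Mask
    Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Few-shot semantic segmentation of grayscale image volumes using
    adaptive local prototype pooling on a metric (cosine) feature space,
    self-supervised training from superpixel pseudo-labels, a multi-scale
    auxiliary prediction head, and an adversarial mask-quality discriminator
    with dual-attentive fusion. Includes a synthetic phantom-volume generator
    for end-to-end desk-scale experiments, the volumetric chunk-pairing
    evaluation protocol, and Dice-coefficient reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    tiff,
    optparse,
    yaml
Config/testthat/edition: 3
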