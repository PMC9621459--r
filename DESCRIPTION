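Package: skinet
Title: Uncertainty-Gated Bayesian Segmentation and Classification of Skin Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage dermoscopy diagnosis pipeline coupling a Bayesian
    MultiResUNet lesion segmenter with a Bayesian convolutional classifier.
    Predictive uncertainty is estimated by Monte-Carlo dropout (epistemic),
    test-time augmentation (aleatoric) and their combination; predictions whose
    normalized predictive entropy exceeds a referral threshold are deferred to
    an expert. Includes saliency attribution (Guided Backpropagation, Grad-CAM,
    Guided Grad-CAM, integrated gradients, XRAI) with a bokeh-effect
    faithfulness benchmark, segmentation and classification metrics, a seeded
    synthetic dermoscopy image generator with pixel-exact masks, and a small
    reverse-mode automatic-differentiation engine that the networks are built
    on. All components run at desk scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
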