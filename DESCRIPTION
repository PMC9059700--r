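Package: fundoprep
Title: Fundus Image Preprocessing, Augmentation and Evaluation for
    Multi-Label Ocular Disease Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable building blocks for chronic ocular disease screening
    pipelines on colour fundus photographs: automatic region-of-interest
    cropping of the circular fundus disc via a gradient circular Hough
    transform (with an Otsu largest-contour baseline), image enhancement
    operators (green-channel extraction, contrast-limited adaptive histogram
    equalisation, Gaussian unsharp blending, multiscale retinex), vessel-mask
    post-processing with pluggable segmentation backends and diffusion
    inpainting, keyword-based relabelling and two-eye aggregation of
    ODIR-style patient manifests, seedable batch-level augmentation,
    multi-label evaluation (macro precision/recall/F1, per-label Cohen's
    kappa, macro AUC), majority-vote ensembling, Grad-CAM contour overlays,
    exact parameter accounting for eleven ImageNet backbone architectures,
    and a seedable synthetic fundus generator with full ground truth so the
    whole pipeline is testable without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
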