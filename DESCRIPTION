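Package: mireg
Title: Unsupervised Affine Co-Registration of Multimodal Brain Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised affine co-registration of multimodal (CT/MR-like)
    brain images built as a regularized spatial transformer: a small
    convolutional localization network predicts six affine parameters in one
    shot, an affine-to-field layer expands them into a dense displacement
    field so field-space regularizers apply, and a differentiable bilinear
    resampler warps the moving image. Training minimizes a differentiable
    soft-histogram mutual-information loss, so no ground-truth deformations
    are needed. Includes a network-free per-pair optimizer, landmark target
    registration error, Dice, Jaccard and Hausdorff evaluation metrics, a
    seeded multimodal head-phantom generator with known ground truth, NIfTI
    and PNG input/output, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    png,
    yaml,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    dplyr,
    tidyr
Config/testthat/edition: 3
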