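Package: segfuse
Title: Multi-Modal MRI Lesion Segmentation with a Promptable Frozen Backbone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prostate-cancer lesion segmentation from registered multi-modal
    MRI (T2W, DWI, ADC) built around a frozen promptable segmentation backbone
    (image encoder, bounding-box prompt encoder, mask decoder).  Trainable
    multi-modal fusion modules combine per-modality image embeddings via
    multi-head cross-attention and two-stage multi-scale modality (channel)
    attention.  A prompt generation module replaces manual bounding boxes:
    coarse prompt-free segmentation, morphological post-processing with
    per-lesion splitting, and iterative box refinement.  Includes a synthetic
    multi-modal phantom generator, a BCE-plus-Dice training loop with a
    two-phase frozen-backbone protocol, global and per-image Dice evaluation,
    and Wilcoxon signed-rank method comparison with Benjamini-Hochberg
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
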