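Package: stainseg
Title: Two-Stage Nuclei Segmentation and Patch-Voting Classification for
    H&E Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Carcinoma versus non-carcinoma recognition of hematoxylin and
    eosin (H&E) stained breast histopathology images built around a two-stage
    nuclei segmentation strategy. Stage one separates the stains by sparse
    non-negative matrix factorization of the optical-density image; stage two
    segments nuclei on the hematoxylin foreground with a saliency-guided,
    marker-controlled watershed. Completed local binary pattern texture
    descriptors and color auto-correlograms are fused and classified with a
    radial-basis support vector machine, and patch predictions are aggregated
    to image labels by majority voting. Includes segmentation and
    classification evaluation (Dice, Hausdorff, accuracy, sensitivity,
    specificity, precision, F1, ROC/AUC) and a Beer-Lambert synthetic H&E
    image generator with ground-truth stain matrices and nuclei masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    tiff,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    pROC,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
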