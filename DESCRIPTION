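Package: filamentr
Title: Whole-Colony Filamentation Quantification and Dose-Response Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the yeast-to-filamentous transition of whole yeast
    colonies from photomicrographs. Implements a six-stage segmentation
    pipeline (resolution standardization, grayscale conversion, Gaussian
    smoothing, binarization, void filling, and dual contour extraction)
    that measures the area of the central colony mass (A_inner) and the
    area enclosed by the boundary spanning all filamentous protrusions
    (A_outer), and reports the normalized filamentation index
    f = (A_outer - A_inner) / A_inner. Includes robust outlier screening
    by modified z-scores, tie-adjusted Kruskal-Wallis omnibus tests with
    Dunn's pairwise post hoc comparisons under Bonferroni adjustment for
    dose-response designs, and a synthetic colony-image generator with
    analytically known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    png,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    jpeg,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
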