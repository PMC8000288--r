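Package: periosr
Title: Evaluation of Resolution-Improvement Methods for Periapical Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate image resolution-improvement methods in the
    context of periodontal bone-loss (PBL) assessment on periapical
    radiographs. Provides from-scratch separable image resampling with
    nearest, bilinear (triangle), bicubic (Keys) and Lanczos kernels plus a
    small trainable three-stage super-resolution CNN; full-reference image
    quality metrics (MSE, PSNR, SSIM) and a downscale-upscale evaluation
    protocol; visual grading characteristics (VGC) analysis of ordinal
    observer ratings, including score distributions, top-down cumulative
    distributions, pairwise VGC curves with trapezoidal AUC, and one-sided
    paired Wilcoxon signed-rank tests; binary-classifier evaluation from
    confusion matrices or scored predictions (sensitivity, specificity, PPV,
    NPV, accuracy, ROC and precision-recall curves); and a synthetic-data
    module generating radiograph-like phantoms with optional bone-loss
    lesions, simulated observer ratings from a latent ordinal quality model,
    and simulated classifier scores with controllable separability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
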