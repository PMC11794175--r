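Package: asckit
Title: Dual-Pathway Automated Evaluation of the Aortic-Stenosis Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of a dual-pathway system for grading
    aortic stenosis (AS) from echocardiography. One pathway scores parasternal
    long- and short-axis videos with a small (2+1)D convolutional network
    trained on ordered severity labels plus auxiliary regression of Vmax, mean
    pressure gradient and aortic valve area, yielding a 0-100 continuum index
    (DLi-ASc) with derived stage cutoffs, Grad-CAM saliency and a 2-D feature
    embedding. The other pathway automates the conventional work-up: spectral
    Doppler envelope segmentation and quantification (Vmax, mean gradient,
    velocity-time integral), LVOT diameter from parasternal long-axis
    segmentation, continuity-equation valve area, guideline staging with
    discordance and low-flow-low-gradient detection, and predictive-entropy
    gating of unreliable measurements. A seeded phantom generator provides
    echo-like videos, label maps, Doppler spectrograms and cohort tables with
    closed-form ground truth so every stage is trainable and testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png,
    pROC,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
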