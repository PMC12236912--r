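Package: brainpad
Title: Brain-Age Prediction and PAD Variance Analysis on Multi-Channel
    Structural MRI Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end brain-age analysis for voxel-based-morphometry style
    structural MRI. Generates multi-site phantom cohorts of four aligned 3D
    channels (gray matter, white matter, T1, warp Jacobian) whose morphology
    encodes a latent age signal, trains a deep ensemble of 3D convolutional
    neural networks to regress age with a mean-absolute-error objective,
    computes the predicted age difference (PAD), and runs the downstream
    inference: group PAD summaries, Levene variance-heterogeneity tests across
    diagnosis and age partitions, ICC(2,k) ensemble reliability, and
    permutation GLMs with variance groups, sign-flipping and max-statistic
    FWER correction. The convolutional layers are implemented natively with
    RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
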