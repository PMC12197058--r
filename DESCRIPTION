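Package: qmedppg
Title: Quaternion-Valued Median Features with PCA Denoising for
    Non-Invasive Blood Glucose Estimation from Four-Channel PPG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Treats a four-channel photoplethysmogram (PPG) recording as a
    sequence of quaternions (one per time sample) and extracts robust
    quaternion-valued median features: the component-wise median, the
    medoid, the unit medoid and the geometric median, all under a
    sign-ambiguous quaternion distance.  The median vectors are denoised by
    projection onto the leading eigenvectors of the recording's 4x4 channel
    covariance and reconstruction, and the resulting 16-dimensional feature
    vectors feed a random-forest regressor for blood glucose estimation.
    Includes a seeded synthetic PPG generator with glucose-dependent pulse
    morphology, a subspace-dimension sweep utility, and evaluation via
    MAE, RMSE, MARD and the Clarke error grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    randomForest,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
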