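Package: hbscreen
Title: Noninvasive Anemia Screening from Conjunctiva Image Color Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for noninvasive anemia screening from cropped palpebral
    conjunctiva photographs. Extracts scalar color features (mean red
    intensity, erythema index, HSI hue), smooths the hemoglobin-ordered
    feature series with a simplified scalar Kalman filter, fits a penalized
    polynomial feature-versus-hemoglobin curve by gradient descent, inverts
    the curve to estimate hemoglobin for new images, and evaluates screening
    performance with a three-level risk evaluation scheme (high-risk,
    doubtful, low-risk) under k-fold cross-validation. Includes a synthetic
    conjunctiva-like image generator so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
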