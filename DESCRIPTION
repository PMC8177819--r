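Package: bpocr
Title: Optical Character Recognition for Seven-Segment Blood-Pressure Monitor Displays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcribes cellphone photographs of an automated oscillometric
    blood-pressure monitor's seven-segment LCD into numeric systolic pressure,
    diastolic pressure and heart rate. Provides the full pipeline: image
    enhancement (grayscale conversion, bilateral filtering, gamma correction,
    adaptive thresholding), contour-based LCD frame localization with
    aspect-ratio filtering, frame normalization, and a multi-digit
    convolutional neural network with three softmax heads and a blank class,
    trained by maximizing the sequence log-likelihood. Includes a synthetic
    scene generator that renders seven-segment displays under controlled
    degradations (blur, darkness, glare, distance, cropping) with exact ground
    truth, plus stratified evaluation utilities (exact-value accuracy, mean
    absolute error, coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
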