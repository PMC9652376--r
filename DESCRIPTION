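Package: faceage
Title: Facial Age-Group Classification with LBP Texture Features and a
    Genetic-Algorithm-Evolved Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Age-group classification from face images in eight brackets
    (0-5 through over 60). Images are converted to grayscale, face-cropped,
    resized and histogram-equalized; block-wise local binary pattern (LBP)
    histograms are projected into an eigenface (PCA) subspace; and a single
    hidden-layer perceptron is trained by damped second-order
    (Levenberg-Marquardt style) backpropagation. The network configuration
    (hidden width, learning rate, damping mu and its decrease factor) is
    evolved by a genetic algorithm with fitness equal to the reciprocal of
    the training mean squared error. Includes a seeded synthetic face-like
    corpus generator emulating the two phases of facial aging (craniofacial
    shape change, then wrinkle texture), and per-group correct
    classification rate (CCR) reporting with confusion matrices.
License: MIT
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
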