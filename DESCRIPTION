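Package: entropytex
Title: Local Non-Additive Entropy Transforms and Fused Deep Features for
    Texture Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a local non-additive (Tsallis-type) entropy transform of
    grayscale images: each pixel is replaced by a reduced entropy of the
    intensity histogram of its square neighbourhood, giving an alternative
    texture representation parameterised by the entropic index q. Descriptors
    are extracted from both the original image and its entropy representation
    with a pluggable pretrained-CNN-style feature extractor, concatenated, and
    classified with principal component analysis followed by linear
    discriminant analysis under standard texture-benchmark split protocols.
    Includes cross-validated selection of q and of the number of principal
    components, synthetic texture generators for end-to-end validation, and a
    perturbed-distribution experiment probing the sensitivity of the entropy
    to the entropic index.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    digest,
    graphics,
    jsonlite,
    jpeg,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
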