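Package: lenstrace
Title: Eyeglasses Lens Contour Extraction by Fourier Shape Morphing and
    Monte Carlo Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts the closed contours of eyeglasses lenses from frontal
    facial images and derives the optometric frame measurements (bridge,
    boxing size, fitting height) from them. Rim shapes are represented by
    truncated Fourier descriptors of their boundary; the search space is
    generated by linearly morphing normalized descriptors of database
    shapes grouped into three rim classes. Candidate rims are fitted by a
    multi-stage procedure: uniform Monte Carlo sampling scored against the
    Euclidean distance transform of a Canny edge map, agglomerative
    clustering of hypotheses by bounding-box overlap, and a random-walk
    hill climb that perturbs one model dimension at a time. A seeded
    synthetic scene generator supplies ground-truth imagery for end-to-end
    parameter-recovery benchmarks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
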