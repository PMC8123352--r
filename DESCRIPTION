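Package: elastoflow
Title: Quantitative Quasi-Static Ultrasound Elastography from CINE Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes spatially resolved Young's modulus and Poisson's ratio maps
    from a B-mode CINE sequence of a quasi-static compression together with a
    load-cell force log. Dense optical flow tracks the speckle displacement with
    correlation-gated redefinition of the reference frame, a two-dimensional
    Savitzky-Golay differentiator converts displacement into strain, the internal
    axial stress under the rectangular transducer footprint is evaluated with
    Love's closed-form solution (with two-compressor superposition), and per-frame
    trustability descriptors gate the frames that enter the final elastogram.
    Includes the mechanical reference estimators (bonded-block compression and
    BASh indentation) and a tissue-mimicking speckle phantom simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pracma,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
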