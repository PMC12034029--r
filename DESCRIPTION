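Package: raga
Title: Rational Approximation of Golden-Angle Radial Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.net", role = c("aut", "cre"))
Description: Design and analysis of golden-ratio based radial k-space sampling
    schemes for dynamic MRI using exact rational approximations built from
    generalized Fibonacci numbers. Provides exact integer-arithmetic scheme
    construction with bijective temporal-to-equidistant index maps,
    retrospective binning with repeating frame patterns, trajectory generation
    and CSV/CFL file interchange, point-spread-function and sidelobe-to-peak
    ratio analysis of sliding spoke windows, a floating-point drift audit of
    angle update rules against an extended-precision reference, and an
    analytic ellipse-phantom simulation with density-compensated adjoint
    reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
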