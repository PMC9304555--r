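Package: somistiff
Title: Somite Tissue Stiffness Mapping and Periodicity Analysis from AFM
    Force Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes atomic force microscopy (AFM) approach force-distance
    curves recorded on embryonic somite strips into spatial maps of the
    apparent reduced elastic modulus K = E/(1-v^2), using Hertz sphere-on-
    half-space contact mechanics with automatic contact-point detection.
    Extracts antero-posterior stiffness profiles, fits the periodic model
    y(t) = C + alpha*sin(omega*t + phi) by nonlinear least squares, and runs
    anterior versus posterior half-sclerotome comparisons with a Shapiro-Wilk
    normality gate (paired t-test, log10 branch, or Wilcoxon) plus cell-
    density comparisons. Includes a seeded synthetic force-curve and
    cell-count generator so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
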