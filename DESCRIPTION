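Package: ramantex
Title: Haralick Texture Analysis of Raman Spectroscopic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial heterogeneity in Raman hyperspectral maps of
    tissue via gray-level co-occurrence matrix (GLCM) texture analysis. The
    pipeline covers spectral preprocessing (cosmic-ray spike removal,
    Savitzky-Golay smoothing, asymmetric least squares baseline subtraction,
    volume normalization), principal component score imaging, GLCM
    construction with four-angle averaging, five Haralick texture features
    (homogeneity, contrast, correlation, entropy, local homogeneity), and
    pairwise Kruskal-Wallis comparison of texture across radiation dose
    groups. A seeded synthetic-data generator emulating multi-mouse Raman
    mapping studies makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pracma,
    yaml,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
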