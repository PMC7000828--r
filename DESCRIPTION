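Package: ugimem
Title: Molecular Data Storage in Combinatorial Ugi Product Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A codec for storing digital data in presence/absence mixtures of
    four-component Ugi reaction products read out by MALDI FT-ICR mass
    spectrometry. Enumerates combinatorial Ugi libraries with monoisotopic
    masses, adduct m/z values and isotope envelopes; maps bit streams onto
    compound-presence matrices either directly (one bit per compound per spot)
    or through sparse constant-weight error-correcting codebooks with
    nearest-codeword decoding; simulates labeled plate spectra (adducts,
    isotope satellites, matrix background, competitive ionization, reaction
    failures, per-spot mass offsets); and recovers data via SNR thresholding
    with ROC-optimal thresholds or supervised multi-peak classifiers. Includes
    plate layout and acoustic transfer-list generation and a command-line
    interface for end-to-end write/read pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    png,
    glmnet,
    ranger
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mzR,
    withr,
    optparse
Config/testthat/edition: 3
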