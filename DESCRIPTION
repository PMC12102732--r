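Package: cimmerge
Title: Merging, Filtering and Trendline Optimization for Multipass
    Cyclic Ion-Mobility HDMS-E Peptide Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hydrogen/deuterium exchange mass spectrometry (HDX-MS)
    peptide mapping with cyclic ion-mobility instruments. Implements the
    drift-time versus drift-FWHM trendline notation used to parameterize
    kernel smoothing of multipass ion-mobility data, iterative per-trendline
    processing plans, replicate merging with retention-time relative standard
    deviation and threshold filtering of peptide-identification lists,
    best-trendline selection, pooling of single- and multipass results
    (multi-sequence) and of several trendline variants (multi-trendline),
    and sequence coverage / redundancy reporting. A synthetic-data simulator
    emulating vendor-style peptide identification exports, including cyclic
    wrap-around of drift times and planted false positives, supports
    end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
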