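Package: framefix
Title: Frame-Shift-Aware Translated Alignment and Correction for Long-Read Metagenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for handling frame-shift errors in long-read metagenomic
    data. Implements frame-shift-aware local DNA-to-protein alignment by
    dynamic programming with a per-event penalty, transcript-based
    frame-shift correction by insertion of unspecified nucleotides,
    range-culling of alignment sets, interval-union LCA taxonomic binning
    of long reads, and assembly-verification statistics (frame-shifts per
    kilobase, concordance score kappa, clone-coverage break-points, repeat
    rates, coverage correlation, genus-level Shannon diversity), together
    with a seeded synthetic-data generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    vegan,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
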