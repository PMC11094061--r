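Package: apashift
Title: Alternative Polyadenylation Shift Analysis from 3'UTR Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies alternative polyadenylation (APA) from per-base 3'UTR
    read coverage using a two-segment breakpoint model of proximal
    polyadenylation-site usage (the PDUI statistic), calls 3'UTR
    shortening and lengthening events between conditions, classifies events
    by time point and CD28-costimulation dependence, scans
    polyadenylation-signal and RBM3 hexamer motifs around cleavage sites,
    performs gene-set overrepresentation tests, and ships a seeded
    synthetic-data generator with known ground truth so the whole pipeline
    can be validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
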