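Package: bpscan
Title: Detection of Intronic Variants that Disrupt Splicing Branchpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds an integrated, consensus-adjusted database of intronic
    branchpoints (BP) mapped to 3'-proximal introns, and detects variants in
    VCF files that disrupt the BP region [-2, 0], annotating each hit with
    motif consensus level, BP rank within its intron, dataset provenance,
    population-frequency and conservation context, and a 0-10 prioritization
    score. Includes a deterministic synthetic-fixture generator for genomes,
    transcript annotations, BP datasets and variant sets, used for
    property-based validation of the detection engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
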