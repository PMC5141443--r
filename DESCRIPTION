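Package: motifexcess
Title: Mutational-Motif Enrichment Analysis for Somatic Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects enrichment of somatic single-base substitutions in
    degenerate DNA sequence motifs relative to their local DNA neighborhood,
    with emphasis on deaminase target motifs (WRC/GYW, TCW/WGA) and the
    hybrid AID-by-CpG motif WRCG/CGYW. Implements the Fm/Fn excess
    statistic with Fisher exact and Monte Carlo significance tests, CpG
    masking, a WRCG-versus-CpG-control contrast, a subsampling power
    procedure, a CpG methylation-ratio association test, and a synthetic
    data generator with planted motif-rate multipliers and methylation
    structure for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
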