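Package: ribodwell
Title: Codon Dwell-Time, Translation-Efficiency and Ribosomal Protein
    Paralog Analyses for Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize paralog-dependent translation from ribosome
    profiling and companion assays: P-site offset inference and codon-resolved
    footprint coverage, per-codon dwell-time estimation conditioned on the
    nascent-chain residue at a chosen distance from the P site, a cross-clone
    cosine-consistency scan over (amino acid x offset) grids, differential
    translation efficiency via a negative-binomial interaction GLM,
    paralog-to-core ribosomal protein expression ratios with rank and scale
    tests, coiled-coil positional enrichment, and polysome-profile
    translation-rate ratios. Includes seeded synthetic-data generators that
    emulate the statistical structure each stage assumes, so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
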