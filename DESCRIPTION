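Package: contextmut
Title: Context-Dependent Mutation Rate Analysis for Mutation Accumulation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes genome-wide and replichore-specific context-dependent
    base-substitution mutation rates from a reference genome, a GenBank
    annotation, and a variant list (VCF or a minimal base-call CSV).
    Detects the replication origin and terminus from cumulative GC skew,
    partitions the chromosome into oriented replichores, tabulates
    trinucleotide (and wider) context occurrence counts, converts variant
    contexts into per-context mutation rates scaled by generations and
    lineage counts, compares rate spectra across organisms by one-to-many
    Pearson correlation ordered by GC content, and exports binned spatial
    mutation data as CSV, JSON and static figures. Includes a synthetic
    fixture generator that plants mutations at known context-specific
    rates so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
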