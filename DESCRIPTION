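Package: fpfilter
Title: Characterization and Hard Filtering of False-Positive Bacterial
    Variant Calls
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking haploid (bacterial) variant-calling
    pipelines and characterizing their false-positive calls. Builds truth
    sets and confident-region BEDs from the consensus of whole-genome
    alignment VCFs plus per-base pileup masking, classifies pipeline VCF
    calls as true or false positives at position/allele granularity,
    extracts nine positional characteristics across caller tag dialects,
    applies empirically motivated hard filters (independently or with
    thinning applied last), and computes filter-efficacy statistics:
    percent of calls removed, percent uniquely removed, and the
    value-added ratio of false-positive to true-positive loss. A seeded
    synthetic-data generator emulates reference genomes, planted truth
    variants, and pipeline call sets with data-deficient and data-surfeit
    false-positive classes, so the whole analysis is testable without
    external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
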