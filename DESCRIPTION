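Package: qscorekit
Title: In Silico Evaluation of 16S rRNA Amplicon Sequencing Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end in silico pipeline for scoring 16S rRNA gene
    amplification and sequencing strategies. Degenerate PCR primers are
    converted to regular expressions and matched exactly against genome
    sequences to extract amplicons; single-end or paired-end Illumina-like
    reads are simulated under a quadratic position-dependent quality decay
    with insertion/deletion/substitution errors; reads are annotated by
    best hit against a curated 16S reference database at a fixed identity
    cutoff, with 16S copy-number-corrected taxonomic profiling. Each
    amplification configuration is scored by a weighted Qscore combining
    amplification-and-mapping sensitivity, multitier taxonomic precision,
    and a read-length-based sequencing cost, optionally weighted by
    habitat-specific OTU abundances estimated from multi-configuration
    count tables. A synthetic genome generator with embedded multi-copy
    16S genes of known lineage supports fully self-contained evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
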