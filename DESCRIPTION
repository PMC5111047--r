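Package: methCaste
Title: Caste- and Sex-Differential DNA Methylation Analysis from
    Replicated Bisulfite Sequencing Counts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing whole-genome bisulfite sequencing count
    data from social-insect caste and sex comparisons. Implements
    spike-in-calibrated binomial methylation calling with false discovery
    control, descriptive methylome geography (metagene and junction
    profiles, CpG observed/expected, methylation deciles, repeat and
    promoter-island profiles), replicated 200-bp window differential
    methylation by a beta-binomial likelihood-ratio test with locally
    pooled dispersion, replicate-shuffling permutation false-discovery
    analyses, stranded expression and antisense integration, and
    position-weight-matrix / miRNA motif enrichment around differentially
    methylated cytosines. A synthetic-data module generates toy genomes,
    replicated methylomes, stranded expression counts and planted motif
    landscapes with the statistical structure the analysis assumes, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    Sequencing, MotifDiscovery, Software
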