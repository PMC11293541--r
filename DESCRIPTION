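Package: ramlseq
Title: Regional Methylation Quantification from Limited-Deamination Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates regional aggregated methylation levels (RAML) from
    standard paired-end sequencing of libraries subjected to limited
    heat-alkaline deamination of 5-methylcytosine. Provides mate-overlap
    trimming of SAM alignments, context- and strand-aware counting of
    C-to-T transitions at CpG sites with mpileup-style quality filters,
    integration of per-region methylation measurements across technologies
    into a benchmarked consensus, two-point calibration against internal
    control regions, conversion of regional transition rates to bounded
    methylation estimates, a margin-based two-proportion z-test for
    differentially methylated regions, and a seeded simulator of
    deaminated reads and pileup counts with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
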