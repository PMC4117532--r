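Package: xcistr
Title: X-Linked STR Screening and Allele-Specific Methylation Readout of
    X-Chromosome Inactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering X-linked core-promoter short tandem repeat
    (STR) markers of X-chromosome inactivation and for quantifying inactivation
    skewing from methylation-sensitive restriction digest QF-PCR data. Provides
    a multi-criterion genome screen (tandem-repeat detection with wraparound
    dynamic-programming alignment, CpG-island proximity, exon and
    pseudoautosomal-region exclusion, methylation-sensitive restriction-site
    scanning), stutter-corrected Xa/Xi lyonization ratios with skewing
    classification, population informativeness statistics, inter-locus
    concordance, trio phasing of the inactive X, and ground-truthed synthetic
    genome and electropherogram cohort simulators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
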