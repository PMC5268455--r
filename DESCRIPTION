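Package: radsolid
Title: RAD-Seq Simulation and Analysis in SOLiD Colour Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for restriction-site associated DNA sequencing (RAD-seq)
    studies built on SOLiD two-base colour-space reads. Provides in-silico
    restriction digestion and enzyme comparison, a synthetic-data generator
    for a two-subpopulation diploid germplasm panel with full library and
    sequencing simulation, restriction-site-anchored read pre-processing and
    colour-space alignment, Bayesian diploid genotype calling with
    multi-sample VCF merging, restriction-site recovery accounting and
    SNP-density diagnostics, population-genetics statistics (observed and
    expected heterozygosity, inbreeding coefficient, private alleles, minor
    allele frequency spectra), LD-kNNi genotype imputation, linkage
    disequilibrium decay curves, call-set concordance, and SNP feature and
    coding-effect annotation from GFF3 gene models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
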