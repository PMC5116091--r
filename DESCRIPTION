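Package: haploregulome
Title: Regulatory Annotation of GWAS Haploblocks with Allele-Specific
    Chromatin Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis toolkit for localizing the regulatory effects of a
    disease-associated haploblock. Builds risk-SNP sets from lead SNPs by
    linkage disequilibrium, defines analysis loci, counts DNase
    hypersensitivity sites per cell type and tests immune versus non-immune
    enrichment, scans both alleles of a SNP against position weight matrices
    with exact p-values to detect transcription-factor motif switches
    (gain/loss, e.g. CTCF), quantifies allele-specific ChIP signal from qPCR
    cycle thresholds and Sanger trace intensities, compares genotype groups
    for windowed H3K27ac coverage and relative expression, and performs a
    simplified 4C-Seq near-cis analysis (restriction maps, bait trimming,
    fragment counting, trend profiles, and genotype-differential interaction
    calls). Includes seeded synthetic-data generators that emulate the
    statistical structure of each assay so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
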