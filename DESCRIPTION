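Package: TrioExome
Title: Trio Whole-Exome Variant Prioritization Under Mendelian
    Inheritance Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate disease variants from parent-offspring
    trio whole-exome sequencing. Reads multi-sample VCFs and pedigrees,
    normalizes variant representation, annotates coding consequences and
    population allele frequencies against user-supplied transcript models
    and frequency tables, filters variants under de novo, X-linked and
    autosomal-recessive inheritance models with genotype-quality, depth,
    allele-fraction and allele-frequency thresholds, and assigns a reduced
    ACMG/AMP evidence set combined into a five-tier pathogenicity class.
    Includes a calibrated synthetic trio-exome simulator with spiked
    causal variants and ground-truth records, plus cohort-level reporting
    of diagnostic yield and phenotype summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
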