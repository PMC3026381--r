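Package: splicepep
Title: Virtual Peptide Databases for Protein Isoform Identification by
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds exhaustive MS-searchable peptide databases covering
    protein isoforms of eukaryotic genes: in-frame exonic peptides,
    annotated and hypothetical splice-junction peptides (exon-exon,
    exon-intron and intron-exon), and single-nucleotide variant peptides
    derived from non-synonymous SNPs. Includes peptide-to-protein mapping
    via multi-pattern string search, peptide sequence queries, reversed
    decoy database construction, and multi-level target-decoy false
    discovery rate estimation, together with a seeded synthetic
    genome/annotation/VCF generator with ground truth and an independent
    brute-force enumeration oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
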