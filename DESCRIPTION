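Package: scnaclonal
Title: Single-Cell Allele-Specific Copy-Number Clonal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying clonal copy-number heterogeneity in
    chromosomally complex tumors from low-coverage single-cell DNA
    sequencing. Simulates clonal copy-number evolution and sparse binned
    read-count / phased B-allele observations with full ground truth;
    infers per-cell haplotype-specific integer copy numbers from
    read-depth ratios and B-allele frequencies; groups cells into clones
    with noisy-cell exclusion and consensus profiles; computes
    whole-genome-doubling-aware aberration, deletion, amplification and
    subclonal-fraction metrics and locus-level loss-of-heterozygosity
    status; reconstructs rooted clone phylogenies under a
    maximum-parsimony interval-event model with event classification
    (gain, del, loh, copy-neutral loh, wgd); and compares samples by
    identical-window concordance and binned copy-number correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    pheatmap,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
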