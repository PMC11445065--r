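Package: startcall
Title: Start Codon Surveys in Bacterial Regulator Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for surveying non-canonical (GTG/TTG) translation start
    codons in bacterial carbohydrate-utilization regulator genes. Provides a
    synthetic genome cohort generator with planted regulator loci and known
    ground truth, an affine-gap Smith-Waterman homology locator, a trainable
    start-codon plus ribosome-binding-site scoring model with fractional
    resolution of ambiguous start sites, cohort-level quality filtering and
    usage aggregation with Mann-Whitney U comparisons and Fitch parsimony
    checks on supplied phylogenies, and competitive-index arithmetic for
    in vivo fitness experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
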