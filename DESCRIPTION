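Package: mirpipe
Title: Small RNA Annotation, Novel miRNA Discovery and Differential
    Expression for Plant Small RNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis toolkit for
    replicated two-condition plant experiments. Reads are collapsed,
    length-filtered (18-28 nt) and assigned to a single category through a
    hierarchical annotation waterfall (structural ncRNA, repeats/mRNA,
    known miRNA catalog, genome, unmapped). Abundances are normalized to
    reads per ten million (RPTM), pooled into miRNA families and placed
    into four abundance tiers. Novel miRNA loci are discovered from
    genome-mapped unannotated reads by extracting flanking precursor
    windows, predicting fold-back structures with a base-pair-maximizing
    dynamic program, scoring the mature:star duplex and requiring
    sequenced miRNA-star support. Differential expression between
    conditions uses a negative-binomial exact test with a common
    dispersion estimated by conditional likelihood and Benjamini-Hochberg
    FDR control. Targets are predicted by mismatch-bounded
    complementarity scanning with optional G:U wobble weighting, and
    target sets are tested for annotation-term enrichment with a
    hypergeometric test. A synthetic-data generator plants miRNA hairpins
    with known fold changes in a toy genome so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
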