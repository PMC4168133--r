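Package: gonomiR
Title: Gonad Small RNA Annotation Cascade and Count-Based Differential
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a gonad small RNA sequencing
    workflow for three pooled libraries (XX ovary, XY testis, YY super-male
    testis): adapter trimming and quality/length filtering of raw reads,
    collapsing to unique tags, a sequential annotation cascade (known
    non-coding RNA and repeat removal, conserved miRNA identification with
    genome support, novel miRNA discovery by hairpin folding of flanking
    genomic sequence, piRNA homology with an ungapped Karlin-Altschul
    E-value filter), reads-per-million normalization, the Audic-Claverie,
    Fisher exact and chi-squared tests with Bonferroni correction and
    explicit up/down/sex-specific call rules, three-set Venn partition
    accounting with a marginal-count solver, hierarchical clustering
    report helpers, and 2^(-ddCt) relative quantification for qPCR
    validation. Includes a ground-truth small RNA library simulator used
    by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
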