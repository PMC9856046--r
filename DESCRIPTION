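Package: pollencrp
Title: Pollen Coat Cysteine-Rich Protein Classification and Molecular Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of small cysteine-rich proteins (CRPs) of
    the Brassicaceae pollen coat. Classifies protein sequences into CRP
    families (PCP-A/DEFL/LCR, PCP-B, SCRL, nsLTP, GASA) by ordered
    cysteine-spacing grammars; post-processes peptide-spectrum match tables
    with target-decoy false discovery rate tiers, replicate merging and
    molecular-weight profiles; performs Fisher term-enrichment tests with
    Benjamini-Hochberg correction; categorizes tissue specificity of gene
    expression after median-of-ratios normalization; and scans codon
    alignments for positively selected sites under the Goldman-Yang codon
    substitution model with site-class models (M0, M1a, M2a, M7, M8),
    likelihood ratio tests and Bayes empirical Bayes site posteriors.
    Includes seeded synthetic-data generators for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
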