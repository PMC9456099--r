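Package: omegascan
Title: Codon-Model Selection Scans for Highland Adaptation Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based scans for shifts in the nonsynonymous/synonymous
    rate ratio (omega) across a fixed species tree: a Goldman-Yang style
    61-state codon substitution model with Felsenstein pruning, branch-model
    and branch-site (Model A) likelihood ratio tests with naive empirical
    Bayes site posteriors, four-fold degenerate site extraction and supergene
    concatenation, screens for lineage-specific and convergent amino-acid
    replacements, and hypergeometric over-representation tests with
    Benjamini-Hochberg correction. Includes a codon-level simulator that
    generates complete synthetic ortholog studies (alignments, trees,
    annotations, planted truth) so every stage is testable without external
    genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
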