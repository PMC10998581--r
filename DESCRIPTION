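Package: clonofate
Title: Clonal Fate Analysis of Semi-Invariant T Cell Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking when and how innate-like T cells (MAIT, iNKT)
    commit to their effector sublineages using paired single-cell TCR
    sequencing. Reads 10x Genomics and AIRR rearrangement tables, applies
    chain-level quality control, groups cells into clones (nucleotide
    identity within an animal) and clonotypes (amino-acid identity across
    animals), and tests whether sublineage commitment depends on TCR
    identity and whether it precedes or follows proliferation via
    permutation null models backed by exact enumeration oracles. Also
    provides CDR3 similarity-graph clustering, positional physicochemical
    profiles, a one-hot positional logistic selection classifier with ROC
    evaluation, a fully specified toy V(D)J recombination model with exact
    amino-acid generation probabilities, and a ground-truthed simulator of
    clonal development under competing commitment scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Matrix,
    glmnet,
    igraph,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
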