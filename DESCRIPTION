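Package: tcemr
Title: T Cell Exposed Motif Attributes and Immunogenicity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes attributes of T cell exposed motifs (TCEMs), the five
    peptide residues of HLA class I bound 9- and 10-mers that contact the T
    cell receptor: their frequency in a reference proteome, their expression
    in cortical thymic epithelial cells, and position-specific scores for
    thymo- and immunoproteasomal cleavage. Provides curation of assay-level
    immunogenicity data into labelled benchmark datasets, normalized BLOSUM62
    peptide similarity with exhaustive best-hit search, ROC-based estimation
    of T cell cross-reactivity cutoffs, naive CD8+ repertoire analyses, and
    pathogen- and HLA-level aggregation of motifs unlikely to mediate
    positive selection. A synthetic-data generator emulates every input with
    planted effects so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
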