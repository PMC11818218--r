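Package: malonmap
Title: Differential Analysis of Lysine Malonylation Sites from Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for relative quantification and differential
    screening of post-translational modification sites (lysine malonylation)
    from label-free intensity tables. Implements per-site centralization to
    relative quantitative values, protein-abundance correction, fold-change
    and coefficient-of-variation significance screening for small replicate
    designs, fold-change (Q1-Q4) binning with Fisher-exact functional
    enrichment and hierarchical clustering of enrichment p-values, motif-x
    style iterative binomial discovery of sequence motifs around modified
    lysines, score-filtered interaction subnetworks, dataset-level QC (PCA,
    intensity summaries), and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
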