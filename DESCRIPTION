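Package: stenoseq
Title: Transcriptomic Dysregulation and Drug Prioritization in Tracheal Stenosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq of iatrogenic tracheal
    stenosis granulation tissue against normal-control samples. Computes
    per-gene signed fold changes, Welch or pooled-proportion p-values and
    Benjamini-Hochberg FDR from a gene-level count matrix, ranks genes by a
    signed change coefficient combining FDR and fold change, prioritizes
    drugs and drug families by how many dysregulated genes they regulate,
    and performs hypergeometric over-representation analysis against
    user-supplied gene sets. Includes a negative-binomial count simulator
    emulating the study design (11 specimen vs 2 control samples, planted
    fold changes, near-silenced genes) plus packaged fixtures encoding the
    published tables of ranked genes and drug-gene interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
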