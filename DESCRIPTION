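Package: raometa
Title: Cross-Platform Expression Meta-Analysis of Rheumatoid and Osteoarthritis Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Harmonizes heterogeneous microarray gene-expression datasets by
    per-array z-scoring on the log2 scale, assembles a multi-study gene
    compendium with presence filtering, quantifies sample-pairwise expression
    divergence between rheumatoid arthritis (RA), osteoarthritis (OA) and
    normal-control (NT) groups, calls differentially expressed genes with a
    from-scratch SAM (Significance Analysis of Microarrays) permutation-FDR
    statistic combined with fold-change criteria, and tests gene-set
    over-representation with the hypergeometric test under
    Benjamini-Hochberg FDR control. A bundled synthetic-data generator
    emulates multi-platform compendium inputs with ground truth so that
    every stage of the workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
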