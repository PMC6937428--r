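Package: kgrepurpose
Title: Drug Repurposing with Uncertain Knowledge Graph Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates drug repurposing hypotheses from literature-mined,
    support-scored heterogeneous knowledge graphs of drugs, diseases and
    genes. Learns confidence-aware bilinear embeddings that regress a
    predicted triple confidence onto literature support, predicts treatment
    links, evaluates them against gold-standard indications (ROC/PR),
    explains predictions via ranked metapaths reduced to their best-supported
    themes, and validates candidate pairs with a permutation-based network
    proximity test on protein-interaction embeddings. Includes a synthetic
    graph generator with planted low-rank structure so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
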