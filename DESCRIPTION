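Package: protscout
Title: Residue-Level Protein Embedding Pre-Filter for Homology Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fast pre-filter for protein homology search. A small 1D
    residual convolutional network embeds each residue of a protein in a
    d-dimensional vector space so that residues likely to share a column in
    a trusted pairwise alignment lie close together. The network is trained
    with a masked N-pair contrastive loss on homologous sequence pairs using
    the AdamW optimizer. At search time, target residue embeddings are
    placed in a vector index (exact or quantized), each query residue
    retrieves its k nearest neighbours by cosine similarity, chance-level
    similarities are removed by a noise gate, and gated scores are summed
    per query-target pair to rank candidate targets for downstream
    alignment. Includes low-complexity masking, a synthetic homolog-pair
    simulator with ground-truth alignments, and recall-versus-filtration
    benchmarking against shuffled decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
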