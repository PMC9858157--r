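Package: ahlp
Title: Hyperlink Prediction for Attribute Hypernetworks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts missing hyperedges (hyperlinks) in attribute
    hypernetworks, i.e. hypergraphs whose nodes carry feature vectors such
    as bag-of-words attributes. A dual-channel encoder combines a
    node-level attention aggregator over the clique expansion of the
    hypergraph with a two-layer node-attribute-node hypergraph convolution
    over the attribute incidence matrix; node embeddings are pooled into
    hyperedge embeddings by hyperedge-level attention and scored by a
    learned function trained with a softplus ranking loss against sampled
    negative hyperedges. Includes exact evaluation metrics (tie-aware AUC,
    recall at k), a planted-community synthetic benchmark generator, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    methods,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
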