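Package: mrmrpath
Title: Biomarker Discovery by mRMR Feature Selection and PPI Shortest-Path Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for transcriptomic biomarker discovery in two-class
    (tumour versus non-tumour) expression studies. Ranks gene probes by
    minimum-redundancy-maximum-relevance (mRMR) mutual information, chooses a
    subset size by incremental feature selection with jackknife-validated
    k-nearest-neighbour classification under the Chou cosine-type distance,
    maps the selected genes onto a confidence-filtered protein-protein
    interaction network, extracts the sub-network of pairwise shortest paths
    between the mapped seed proteins, and assesses each sub-network protein's
    path-occurrence betweenness against random seed sets with a permutation
    test. Includes simulators for expression matrices with planted
    informative, redundant and noise probes and for scale-free interaction
    networks with planted hubs, so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
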