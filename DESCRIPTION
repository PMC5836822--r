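Package: netenrich
Title: Functional Link Enrichment of Gene Sets in Typed Molecular Networks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a gene or protein set is more densely connected in a
    global typed molecular-interaction network than expected by chance. The
    induced subnetwork's link count is compared against degree-matched
    node-permutation random networks, with a normal-approximation test or a
    Monte-Carlo permutation p-value, an edgeless-network convention,
    interaction-type filtering, four negative-control set models, ROC/AUC
    benchmarking with the classifier score 1 - p, and a self-contained
    synthetic-world generator (power-law background with planted functional
    modules) so the whole pipeline can be exercised without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'interactionTypes.R'
    'AllClasses.R'
    'readers.R'
    'subnetwork.R'
    'nullModel.R'
    'enrichment.R'
    'negativeControls.R'
    'benchmark.R'
    'syntheticData.R'
    'cli.R'
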