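Package: lombarde
Title: Confident Explanatory Subnetworks from Putative Transcriptional
    Regulatory Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts from a putative transcriptional regulatory network
    (transcription factor/binding site affinity arcs scored by p-values,
    optionally extended with experimentally validated regulations) the
    subnetwork that explains a set of observed co-expressed gene or operon
    pairs. Each co-expressed pair is explained by a directed regulatory
    cascade between the two genes or by two divergent cascades from a
    common regulator; arcs carry discrete costs obtained by equal-frequency
    binning of affinity p-values, and the output is the union of all
    minimum-cost explanations across pairs. Includes exhaustive-search
    oracles for the NP-hard global variants of the optimisation problem,
    evaluation statistics (degree distributions, radiality centrality and
    central-regulator ranking, hypergeometric enrichment of validated
    arcs), a synthetic network generator with planted co-expression pairs,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'alt-optima.R'
    'cli.R'
    'cost-scheme.R'
    'explain.R'
    'graph-model.R'
    'lombarde-package.R'
    'netstats.R'
    'synthetic.R'
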