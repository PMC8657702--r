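Package: pcmbench
Title: Proteochemometric Binding Classification with Pluggable Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trains and evaluates protein-ligand binding classifiers from
    interchangeable compound and protein descriptor backends (precomputed
    embedding tables or built-in handcrafted baselines). Implements random,
    leave-compound-cluster-out and leave-protein-out evaluation regimes, a
    feedforward proteochemometric classifier together with a
    no-interaction-terms baseline, early-enrichment metrics (Matthews
    correlation coefficient and BEDROC), per-protein top-decile overlap,
    nearest-neighbour split-difficulty diagnostics, descriptor-marginal
    aggregation and paired significance analysis, plus a synthetic
    bioactivity simulator so every pipeline stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    withr,
    yaml,
    Biostrings,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
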