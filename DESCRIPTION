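Package: localweb
Title: Local Co-Occurrence Network Properties of Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers exact probabilistic co-occurrence and co-exclusion
    associations between taxa across a metacommunity (the hypergeometric
    model of pairwise spatial association), assembles them into signed
    metawebs, projects the metaweb onto each sample to obtain local
    association networks, and summarises every sample by community-level
    network properties (modularity, clustering coefficient, average path
    length, connected components, co-occurrence and co-exclusion edge
    proportions). Includes randomization null models with z-scores,
    ordination and diversity statistics, variation partitioning, mixed
    models of properties on management and weather, a pathogen-presence
    model, and a fully ground-truthed synthetic metacommunity generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    lme4,
    lmerTest,
    car,
    glmnet,
    jsonlite,
    biomformat,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
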