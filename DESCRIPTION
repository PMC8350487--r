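Package: connectogene
Title: Stepwise Connectomics and Imaging-Transcriptomics of Divergent Thinking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to relate resting-state functional connectivity to
    cortical gene expression and creative ability. Implements stepwise
    functional connectivity chains and their local and distributed
    variants, per-node weighted-degree maps, node-wise general linear
    models of connectivity on divergent-thinking scores with Monte-Carlo
    cluster-extent correction, region-level parcellation of statistic
    maps, a transcriptome-wide spatial-similarity screen with an
    empirical null, gene-set overrepresentation with fold enrichment and
    Bonferroni control, closeness centrality of candidate genes in an
    interaction network, and semantic-distance scoring of divergent
    thinking from word embeddings. A synthetic-data module generates
    every input with planted effects so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
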