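Package: spongenet
Title: Genome-Wide Competing Endogenous RNA Network and Group Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers a genome-wide competing endogenous RNA (ceRNA) network
    and ceRNA groups from miRNA and gene expression, gene-centric copy-number
    aberration, and miRNA-target binding scores. miRNA-target interactions
    are filtered by expression anticorrelation with bootstrap consensus, by a
    per-sample Interaction Regulation statistic quantifying mutual expression
    abundance, and by a per-gene Effective Regulation statistic summarizing
    total miRNA pressure. Candidate gene pairs are screened by a
    common-regulator hypergeometric test, copy-number-adjusted partial
    correlation, and a Collective Regulation statistic; amplified indirect
    edges are removed by closed-form network deconvolution; ceRNA groups are
    detected with Walktrap community detection, validated against three
    group conditions, and integrated into the final network. A seeded
    synthetic-data generator with planted ceRNA structure supports
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
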