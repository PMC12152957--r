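Package: bnpah
Title: Enumeration and Structure-Property Analysis of BN-Doped
    Cata-Condensed Polybenzenoid Hydrocarbons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exhaustive enumeration of cata-condensed polybenzenoid
    hydrocarbon scaffolds as dualist trees on the hexagonal lattice
    (helicenes included), generation of all unique (BN)1 substitution
    isomers deduplicated by molecular-graph automorphisms, five
    connectivity-only structural descriptors (ring count, longest linear
    stretch, inner/outer heteroatom placement, shortest B-N path length,
    and disrupted-ring count), geometry-based connectivity filtration,
    a synthetic electronic-property generator emulating DFT-derived
    trends, and a gradient-boosted regression and feature-ablation stage
    for structure-property analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
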