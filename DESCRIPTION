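Package: ceRNAnet
Title: Competing Endogenous RNA Network Inference for Small Two-Group
    RNA-Seq Designs
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers circRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    regulatory networks from feature-by-sample count tables of a two-group
    design. Provides class-specific differential-expression calling (fold
    change plus p or FDR gates), canonical miRNA seed-match target
    prediction (6mer, 7mer-A1, 7mer-m8, 8mer sites), Spearman
    anti-correlation and Pearson co-expression screening, a hypergeometric
    shared-sponge test, tripartite network assembly with triad enumeration
    and GraphML export, generic hypergeometric over-representation
    analysis against GMT gene sets, and a negative-binomial synthetic-data
    generator that plants known sponge triads so the whole pipeline can be
    verified end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
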