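Package: ecoconv
Title: Convergence Genomics of Ecomorphs: Selection Screens, Relative
    Rates, and Gene Reuse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to aggregate genome-wide branch-site selection screens
    across repeatedly evolved ecomorphs, associate relative evolutionary
    rates with binary foraging traits via Kendall rank correlation, filter
    protein-convergence (omega_c) branch-pair evidence, regress pairwise
    gene reuse on divergence time, and run hypergeometric gene-set
    enrichment with matched-size randomization nulls. Includes a synthetic
    data generator (pure-birth chronograms, per-gene rate matrices with
    foreground acceleration, selection indicators with age-decaying reuse,
    and annotation sets with planted enrichment) so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    yaml,
    fgsea,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
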