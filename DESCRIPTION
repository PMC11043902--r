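Package: parafd
Title: Functional Alpha and Beta Diversity of Parasites and Their Hosts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking the functional diversity of parasite
    assemblages to that of their hosts and to the off-host environment
    across biogeographic regions. Builds neighbour-joining functional
    trees from mixed-type trait tables (Gower distance), computes three
    tree-based components of functional alpha diversity (richness,
    divergence, regularity), fits generalized least squares models on a
    pseudo-phylogeny of regions derived from species composition with
    forward stepwise selection and Moran's I residual diagnostics,
    computes branch-based Ochiai functional beta diversity, and fits
    generalized dissimilarity models with monotone I-splines and
    matrix-permutation variable importance. Includes a synthetic realm
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    geosphere,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
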