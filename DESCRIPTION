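Package: ecoassembly
Title: Null-Model Inference of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Phylogenetic and taxonomic null models for partitioning the
    ecological processes that assemble microbial communities along
    environmental gradients. Computes abundance-weighted beta mean nearest
    taxon distances and the beta nearest taxon index (betaNTI), the
    Raup-Crick metric on Bray-Curtis dissimilarity (RC-bray), and the
    five-way classification into variable selection, homogeneous selection,
    homogenizing dispersal, dispersal limitation and undominated processes.
    Also provides abundance-based beta-null deviations (Bray-Curtis and
    weighted UniFrac), Sloan neutral-community-model fitting of migration
    rates, Levins' habitat niche breadth, ensemble co-occurrence network
    inference with permutation tests and Brown's method for dependent
    p-values, observed-over-random (O/R) association ratios, Biolog
    EcoPlate average well colour development, first-order soil organic
    carbon mineralization kinetics, and a synthetic metacommunity generator
    with known assembly regimes for end-to-end process-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Matrix,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
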