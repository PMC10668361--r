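Package: reefnet
Title: Co-Occurrence Network Stability Analysis for Coral Microbiome Count Tables
Version: 0.1.0
Authors@R: person("Reefnet", "Maintainers", email = "maintainers@reefnet.example.org", role = c("aut", "cre"))
Description: An end-to-end, seed-deterministic pipeline for asking whether one
    microbial community has a more stable ecological network than another.
    Starting from an ASV (amplicon sequence variant) count table it applies
    relative-abundance, prevalence and rarefaction filters, compares
    communities by PERMANOVA on Bray-Curtis distances, builds signed Spearman
    co-occurrence networks under |rho| and p-value thresholds, contrasts their
    topology with Erdos-Renyi random-graph ensembles (small-world coefficient,
    modularity), classifies nodes into network hub / module hub / connector /
    peripheral roles from within-module connectivity (Zi) and participation
    (Pi), and compares networks by bootstrapped two-sample Kolmogorov-Smirnov
    tests on node centralities. A Gaussian-copula synthetic community
    generator with planted correlation modules, connector taxa and group
    effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
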