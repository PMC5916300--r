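Package: reefQE
Title: Hierarchical Apportionment of Quadratic Entropy and Phylogenetic
    Signal for Nested Reef Communities
Version: 0.1.0
Authors@R:
    person("Reef", "Assembly Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for trait-based and phylogeny-based community assembly
    analysis of nested (atoll / site / colony) species abundance designs.
    Implements Rao's quadratic entropy and its even-weighted additive
    apportionment across three nested spatial scales for unbalanced designs,
    with scale-specific permutation null models and standardized effect
    sizes; Gower mixed-trait and raw nucleotide p-distance matrices;
    Blomberg's K statistic with and without intraspecific measurement error;
    the Fitch/Hartigan parsimony count and Maddison-Slatkin randomization
    test for nominal traits; a fecundity trait built from egg counts and egg
    volumes with body-size interpolation; a gene-by-gene robustness harness;
    and seeded synthetic-data generators (Yule trees, Brownian and Mk trait
    evolution, nested metacommunities under neutral, filtering and limiting
    similarity assembly) so the whole pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    mgcv,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
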