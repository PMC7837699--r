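Package: starterscope
Title: Community, Biogeography, Interaction, and Function Analysis for
    Sourdough Starter Microbiomes
Version: 0.1.0
Authors@R:
    person("Starterscope", "Maintainers", email = "maintainers@starterscope.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for sourdough-starter (and similar
    fermented-food) microbiome surveys: community-table normalization,
    Bray-Curtis dissimilarity and Ward.D2 clustering, probabilistic
    (hypergeometric) pairwise species co-occurrence with expected-count
    filtering and Bonferroni correction, Haversine distance-decay and
    k-means geographic regioning, indicator-taxon screens with FDR
    control, Mantel/PERMANOVA/NMDS/Kruskal-Wallis permutation statistics,
    serial-transfer competition persistence calls with a Monte-Carlo
    concordance test against in-situ co-occurrence signs, logistic
    dough-rise kinetics, volatile-compound preprocessing and
    community-function linkage, patristic-distance species assignment,
    and a seeded synthetic-data generator emulating the statistical
    structure of a large starter survey so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
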