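Package: medrefugia
Title: Phylogeographic Statistics and Multi-Model Paleoclimate Refugium
    Delimitation for Mediterranean Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-locus phylogeography and paleoclimate-based
    glacial refugium delimitation. The molecular arm provides haplotype
    collapsing, p-distances, nucleotide and haplotype diversity, Fu's Fs and
    the Ramos-Onsins & Rozas R2 neutrality tests with fixed-S coalescent
    significance, Mantel isolation-by-distance tests, grid-based bootstrap
    diversity and rarity mapping, statistical-parsimony haplotype networks
    with 95%/99% connection limits, and single-threshold GMYC lineage
    delimitation on ultrametric trees. The niche-modeling arm computes
    bioclimatic variables from monthly climatologies, change-factor
    downscaling of paleoclimate anomalies, a shared principal-component
    environmental space, maximum-entropy suitability models with partial-ROC
    evaluation and mobility-oriented-parity extrapolation masking, and
    consensus refugium delimitation across general circulation models and
    time slices. A synthetic-data module generates geo-referenced haplotype
    datasets and multi-model climate suites with known truth so every stage
    can be verified at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    geosphere,
    igraph,
    optparse,
    xml2,
    yaml
Config/testthat/edition: 3
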