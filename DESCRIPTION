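Package: zoopim
Title: Integrative Zooplankton Imaging and Multi-Marker Metabarcoding Analysis
Version: 0.1.0
Authors@R: person("Arctic Plankton", "Toolkit", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify mesozooplankton communities from flatbed-scanner
    image exports (abundance, ellipsoid biovolume and dry-mass biomass per
    cubic metre of filtered water) and from multi-marker metabarcoding ASV
    tables (COI, 18S V4, 18S V9), to normalize sequence reads across size
    fractions (NSRA scaling and merge), to harmonize taxon lists across
    methods, and to run the comparative community statistics: Shannon and
    Jaccard diversity, matrix correlations, PCA with passive vectors,
    Bray-Curtis nMDS with permutational environmental vector fitting, and
    Ward/k-means station clustering. Ships a forward simulator of the whole
    observation chain (latitudinal community gradient, net tow, sieve
    fractionation, Motoda splitting, imaging measurements,
    biomass-proportional reads with amplification bias) so the full pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
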