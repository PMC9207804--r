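Package: soilcooc
Title: Soil Microbial Co-Occurrence Networks Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds signed, thresholded Spearman co-occurrence networks from
    OTU count tables and relates their topology to environmental gradients.
    Implements core-taxon filtering by abundance rank and prevalence,
    Benjamini-Hochberg thresholded correlation graphs, node- and
    network-level topological features with per-sample subnetworks,
    pH-preference ecological clusters, Levins' niche breadth, Zi-Pi keystone
    classification, natural-connectivity robustness under random node
    removal, and permutation-based driver attribution (multiple regression
    on distance matrices and Mantel tests). Ships a seed-controlled
    synthetic community generator with planted pH preferences and guild
    structure so every stage has a recovery test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
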