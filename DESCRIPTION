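Package: mutpanel
Title: Targeted Sequencing Panel Design from Somatic Mutation Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs targeted-sequencing panels that maximize somatic point
    mutation capture per base pair sequenced. Mutation positions are clustered
    into hotspots using an amplicon-length gap threshold, candidate
    fixed-length amplicons are generated around each hotspot, and an optimal
    panel is selected under a total base-pair budget by greedy forward
    selection or by a pseudo-exhaustive comprehensive search that splits large
    hotspots at minimum-coverage valleys and enumerates amplicon combinations
    within each split region. Includes a brute-force sliding-window selector
    for validation, a conventional consecutive-tiling baseline, capture
    efficacy evaluation with paired nonparametric testing, dataset
    reproducibility checks, optimal sample-size estimation, and a synthetic
    mutation-data generator with planted hotspot structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    vcfR
Config/testthat/edition: 3
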