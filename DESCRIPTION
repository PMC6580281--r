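Package: paleomyco
Title: Paleoclimate Legacies in Soil Fungal Community Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking late-Quaternary climate change and contemporary
    environment to soil fungal community composition. Implements the modified
    Raup-Crick null-model dissimilarity, climate-change velocity and anomaly
    surfaces from paired present/LGM grids, multiple regression on distance
    matrices (MRM) with permutation inference and Bonferroni forward selection,
    d-separation causal path analysis with Fisher's C goodness-of-fit test and
    range-standardized path coefficients, multi-group variation partitioning by
    inclusion-exclusion, and distance-based PerMANOVA. A synthetic-data module
    generates complete study datasets (OTU tables, plant and soil covariates,
    paired climate grids) with known causal structure so the full inference
    chain can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
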