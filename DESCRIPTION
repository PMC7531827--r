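Package: wbcs
Title: Worldwide Bioclimatic Classification of Gridded Monthly Climatologies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the climatic parameters and bioclimatic indices of the
    Rivas-Martinez Worldwide Bioclimatic Classification System (WBCS) from
    gridded monthly climatologies (mean daily minimum and maximum temperature
    and precipitation totals), assigns the seven hierarchical bioclimatic
    units (continentality, macrobioclimate, bioclimate, bioclimatic variant,
    thermotype, ombrotype and isobioclimate) with a versioned, auditable
    threshold ruleset, and compares classified grids across climate periods:
    area tables, per-cell change and stability masks, aggregate warming and
    aridification trends, and bioclimatic-diversity loss. Includes a
    deterministic synthetic-climatology generator emulating strongly
    continental mid-latitude grids so the whole pipeline can be exercised
    without external data, plus CSV and GeoJSON export of classified grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
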