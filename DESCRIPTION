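Package: farmscapes
Title: Farm-Level Ecosystem Service Indicators for Agricultural Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a suite of nine spatial ecosystem-service indicators
    (landscape variation, cropland distance to non-cropland, semi-natural
    grassland, small-scale habitats, crop-sequence quality, roadside
    variation, accessibility, visitors and protected-area coverage) for
    individual farms from planar landscape data, groups farms by type,
    livestock density and size, and compares each farm group to surrounding
    reference farms with a local area-weighted difference statistic, Welch
    t-tests and a Welch-mirrored Cohen's d. Includes a deterministic
    synthetic-landscape generator for validation and power studies, Spearman
    redundancy screening of indicators, gridded regional summaries, and a
    configured, resumable analysis pipeline with GeoJSON/CSV/YAML I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    deldir,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sp,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
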