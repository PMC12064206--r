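Package: leisurenet
Title: Leisure Activity Networks from Time-Use Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Build and analyse co-participation networks of leisure
    activities from long-format time-use diaries. Provides a synthetic
    diary generator for two respondent groups stratified by subjective
    well-being, inclusion/exclusion filtering and group assignment,
    bipartite (person x activity) incidence matrices, projection to
    weighted one-mode activity networks via thresholded cosine
    similarity, the classical network distribution indices (density,
    inclusiveness, mean distance, isolated nodes), tied degree-centrality
    rankings, modularity-based cohesive-subgroup detection, and quadratic
    assignment procedure (QAP) permutation tests for correlating
    networks, together with broom-style tidiers and ggplot2 plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
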