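Package: symbionet
Title: Tripartite Host-Symbiont Co-Expression Networks and Constrained Ordination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene-expression interactions among a mite host
    and two bacterial symbionts from meta-transcriptomic count tables.
    Implements permutation-based Spearman edge calling between expression
    compartments, per-gene network scores with hub filtering, distance-based
    redundancy analysis (dbRDA) on Bray-Curtis or robust Aitchison distances
    with Monte Carlo permutation tests and forward model selection, ANOSIM,
    rank-based and FDR-controlled condition contrasts, and a seeded synthetic
    data generator with planted cross-compartment correlation structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
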