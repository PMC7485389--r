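Package: comorbnet
Title: Comorbidity Network Inference from Discharge Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds significance-filtered disease comorbidity networks from
    hospital discharge records coded in ICD-10: pairwise co-occurrence is
    tested with a one-sided hypergeometric test under Benjamini-Hochberg
    false-discovery-rate control, the resulting undirected network is
    summarised by topology metrics (density, average degree, Freeman degree
    centralization, clustering), decomposed into flow-based modules by
    minimising the two-level map equation over PageRank visit rates, and
    linked to molecular mechanism through disease-gene annotations: shared
    genes and Jaccard similarity for comorbid disease pairs, and pathway
    over-representation of the shared-gene lists. Includes age-stratified
    network construction, a synthetic cohort and annotation generator with
    planted ground truth for end-to-end validation, and tidy/ggplot2 result
    interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
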