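Package: switchflow
Title: Switch-Gene Discovery in Gene Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects switch genes in case/control gene expression data via
    co-expression network cartography. Builds a signed Pearson correlation
    network over differentially expressed genes, partitions it with replicated
    k-means and scree-based model selection, places every node on the heat
    cartography plane (within-module degree z-score Zg, clusterphobic
    coefficient Kpi, average Pearson correlation coefficient APCC), classifies
    date/party/fight-club hubs, and extracts switch genes (low Zg, high Kpi,
    negative APCC). Includes sex-stratified pipeline runs, Welch-test contrast
    tables, set-overlap decomposition, hypergeometric over-representation
    analysis, degree/betweenness ranking of regulators, network robustness
    curves under targeted node removal, and a synthetic-data generator with
    planted module, switch-gene, differential and sex-effect ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
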