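Package: panelmap
Title: Cross-Dataset Gene Panel Mapping and lncRNA-mRNA Network Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps bulk-derived up-regulated gene panels onto multiple
    single-cell RNA-seq datasets, matches clusters across datasets by
    mean-profile correlation and reciprocal marker overlap, isolates a
    condition-specific activated stromal-cell signature shared across
    datasets, screens for correlated genes with protein-class annotation,
    and assembles a bipartite lncRNA-mRNA interaction network with
    ROC-based panel evaluation. Includes a seeded negative-binomial
    synthetic-data generator that emulates multi-dataset single-cell
    cohorts with a planted stromal signature, pseudo-bulk case/control
    cohorts, a microarray-like PBMC matrix carrying lncRNAs, and an
    interaction table with planted edges, so the full pipeline runs and
    is validated without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
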