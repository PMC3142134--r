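Package: coexmod
Title: Condition-Dependent Gene Coexpression Module Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Weighted gene coexpression network analysis pipeline for
    annotating genes by module membership across multiple microarray
    experiments. Maps probe sets to genes by exact probe alignment,
    averages replicates, filters genes by coefficient of variation,
    builds an unsigned soft-thresholded correlation network, computes
    topological overlap, detects modules by a static cut of the
    average-linkage dendrogram, summarizes module expression trends as
    Z-scores with anti-correlated sign groups, tests modules for Pfam
    domain enrichment with the hypergeometric distribution under
    Bonferroni control, and compares module memberships between
    per-experiment (condition-dependent) and pooled
    (condition-independent) analyses. Includes a synthetic-data
    generator that plants known modules, probe-set layers and domain
    annotations so that every stage can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    methods,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
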