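Package: agesurv
Title: Aging-Related Transcript Discovery and Survival Linkage in Paired
    Normal/Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers transcripts whose expression in normal tissue of
    cancer patients depends on chronological age, using a pair of linear
    models (age alone, and age adjusted for principal components not
    correlated with age), bootstrap stability filtering, and per-sample
    increasing/decreasing expression indices.  Links indices, genes and
    network modules to survival through univariate Cox models,
    Kaplan-Meier curves with median split and log-rank tests; calls
    paired tumor-vs-normal differentially expressed genes; detects
    protein-interaction network modules with a graph diffusion kernel,
    average-linkage clustering and a dynamic tree cut; and compares
    feature sets for survival prediction with repeated cross-validated
    logistic regression AUCs.  Ships a synthetic-cohort generator with
    planted ground truth for every stage and a single-command pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    withr,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
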