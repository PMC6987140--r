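Package: threec
Title: Categorize-Cluster-Classify Subtype Discovery for Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the three-step Categorize-Cluster-Classify (3C)
    strategy for data-driven discovery of disease subtypes in mixed
    clinical/biomarker cohorts. Variables are categorized into assigned
    diagnoses (DX), clinical measurements (CM) and potential biomarkers
    (pBM); CMs are screened by two-stage random-forest variable importance
    and clustered by k-medoids with Manhattan distance, with gap-statistic
    guidance on the number of clusters; pBMs are then tested across the
    resulting clusters (Kruskal-Wallis with Benjamini-Hochberg FDR control,
    pairwise Wilcoxon rank-sum at a Benjamini-Bogomolov adjusted level) to
    build per-subtype biomarker signatures. Includes a synthetic-cohort
    generator with planted ground truth, preprocessing (complete-case
    filtering, redundancy removal, domain composites, monotone transforms),
    quantile-profile and signature-heatmap reporting, and a reproducible
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
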