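Package: juncnov
Title: Cancer-Specific Splice Junction Novelty and Sharedness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Indexes exon-exon splice junction evidence across tumor,
    normal-tissue and auxiliary RNA-seq cohorts, classifies each junction
    through a hierarchical cancer-specificity filter against tissue-matched
    and pan-tissue panels of normals, quantifies junction prevalence and
    sharedness within and across cancer cohorts, assigns putatively
    cancer-specific junctions to adult, developmental, placental and stem-cell
    evidence sets to derive the unexplained class, and runs the accompanying
    cohort statistics (junction burden versus mutational burden regression,
    splicing-factor mutation stratification, Fisher sharedness tests and
    Kaplan-Meier survival). A synthetic multi-cohort generator with planted
    ground truth makes every stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    vctrs,
    survival,
    IRanges,
    S4Vectors,
    DBI,
    RSQLite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
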