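Package: microdys
Title: Dysbiosis Scoring and Community Statistics for Small-Intestinal Microbiome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for duodenal-aspirate 16S taxon count tables:
    a reference-cloud dysbiosis index on centered log-ratio (Aitchison) geometry
    with a two-standard-deviation classification rule and an orthogonal
    logit-scale validation, a random-forest out-of-bag symptom index with
    shadow-feature (Boruta-style) selection and DeLong AUC confidence intervals,
    permutation-based differential abundance testing with prevalence and
    abundance filters and per-rank Benjamini-Hochberg FDR control, alpha and
    beta diversity with PERMANOVA and ordination statistics, and a Monte-Carlo
    Dirichlet-multinomial power analysis. A synthetic-cohort generator with
    recorded ground truth makes every stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    randomForest,
    pROC,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    picante,
    yaml,
    optparse
Config/testthat/edition: 3
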