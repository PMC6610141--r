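Package: edumr
Title: Univariable and Multivariable Mendelian Randomisation for
    Education, Cognition and Smoking Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for estimating the direct and total
    causal effects of educational attainment and general cognitive ability on
    smoking behaviour with Mendelian randomisation. Provides individual-level
    estimators (two-stage least squares with polygenic-score instruments,
    multivariable MR, Sanderson-Windmeijer conditional F statistics), two-sample
    summary-data estimators (Wald ratios, inverse-variance weighting,
    multivariable IVW, MR-Egger, modified Cochran Q with per-SNP outlier
    removal), phenotype construction helpers, allele harmonisation, LD pruning,
    and a synthetic-data module that simulates individual-level cohorts and GWAS
    summary statistics under explicit causal diagrams (mediation, dynastic
    effects, selection) so every estimator can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lmtest,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
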