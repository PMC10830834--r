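Package: breedgain
Title: Genetic-Gain Analysis for Plant Breeding Programs via Two-Stage
    Pedigree-BLUP of Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating realized genetic gain in long-running
    breeding programs from unbalanced historical multi-environment trial
    data. Implements a two-stage weighted mixed-model analysis: stage one
    extracts per-year genotype BLUEs with a days-to-flowering covariate and
    design-specific blocking factors; stage two combines the weighted BLUEs
    in a pedigree-BLUP model using the additive relationship matrix built by
    the tabular method, yielding breeding values, prediction error
    variances, reliabilities and Cullis heritabilities. Genetic trends are
    estimated by regressing breeding values on year of origin (or release,
    or testing) with linear and loess fits; elite panels are selected by
    breeding-value and reliability thresholds; genotype stability is ranked
    from an environment-centered GGE singular value decomposition. A
    synthetic breeding-program generator with known ground truth (crossing
    schemes, truncation selection, heterogeneous trial designs and error
    variances, missingness and outlier contamination) supports end-to-end
    validation. The REML/Henderson mixed-model engine is self-contained and
    supports arbitrary pedigree covariance structures on random terms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
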