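Package: sizerange
Title: Intraspecific Variation in Reported Maximum Body Size of Marine Metazoans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies disagreement among published reports of maximum body
    size within marine animal species. Computes per-species maximum-size
    summaries and the log10 range statistic, fits zero-inflated gamma hurdle
    regressions (logit zero component, log-link gamma conditional component)
    with AICc model competition, estimated marginal means and Tukey-adjusted
    contrasts, compares smallest/mean/largest size distributions
    (Kolmogorov-Smirnov, centered-variance F, Spearman, D'Agostino skewness),
    runs a rank-stability randomization over repeated draws of one reported
    maximum per species, compares intra- to interspecific ranges across the
    taxonomic hierarchy, and flags species with extreme ranges as candidate
    unit or colony-versus-module errors. Includes a synthetic-cohort generator
    with known ground truth so the whole pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    emmeans,
    knitr,
    rmarkdown
Config/testthat/edition: 3
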