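Package: metaboratio
Title: Pathway-Centric Ratio Analysis of Targeted Metabolomics Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clusters cell lines by metabolic pathway activity inferred from
    targeted metabolomics panels. Implements replicate-anchored removal of
    unwanted variation (RUV-III) for batch correction, transformation of
    log10 metabolite concentrations into pathway product-to-precursor ratio
    features, consensus K-means clustering under a 1 - Pearson correlation
    distance with gap-statistic, elbow and silhouette selection of the
    number of clusters, cluster contrasts by unpaired t-tests with
    Benjamini-Krieger-Yekutieli two-stage FDR control, and differential
    mining of loss-of-function and drug-sensitivity screen tables. Includes
    a synthetic-data generator that emulates the batch structure, replicate
    design and planted pathway-ratio cluster signal of such panels, so the
    whole pipeline is testable without any external download.
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
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
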