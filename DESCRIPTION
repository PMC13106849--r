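Package: honeybiogeo
Title: Biogeography of Honey Bee mtDNA Lineages from Honey Environmental DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the geographic and temporal distribution of
    Apis mellifera mitochondrial DNA lineages (A, C, M) detected in honey,
    treated as a pooled environmental-DNA matrix. Provides a seeded synthetic
    data generator emulating beekeeper sampling structure, lineage pattern
    tabulation with deduplication to unique beekeeper-year samples, logistic
    cline regression on latitude, longitude and production year fitted by
    iteratively reweighted least squares, the Modified Mann-Kendall trend
    test with Hamed-Rao autocorrelation-corrected variance for per-beekeeper
    lineage diversity series, random-effects meta-analysis of Kendall's tau
    with REML between-study variance and geographic moderators, an analytic
    model of pooled detection probability and the honey-versus-individual-bee
    sensitivity factor, and within-year beekeeper consistency summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
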