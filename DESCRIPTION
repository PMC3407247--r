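Package: chemoscreen
Title: Two-Tier Integrative Screening of Gene Expression and
    Nucleoside-Analogue Drug Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Links gene expression to nucleoside-analogue drug response with
    a two-tier integrative screen: a panel-wide Pearson correlation screen of
    probe-level expression against log10(GI50) with exact r-to-t-to-P
    conversion, a paired sensitive/resistant differential screen with
    empirical-Bayes moderated statistics, Benjamini-Hochberg FDR and a
    directionally-congruent fold-change filter, and directional intersection
    of the two gene signatures. Includes the companion assay-level
    calculations (kinetic NADPH rates, subtraction-based G6PD-specific
    activity, flow-cytometry cell-death normalization, geNorm-style reference
    factors) and seeded synthetic-data generators with planted signals so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
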