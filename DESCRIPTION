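Package: mpnmethane
Title: Tracer-Based Rates of Methylphosphonate-Driven Aerobic Methane
    Formation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative workflow for closed-vessel 13C-tracer incubations
    measuring aerobic methane formation from methylphosphonate in
    oligotrophic seawater. Converts serially subsampled headspace
    measurements into dilution-corrected excess 13C-CH4 time series,
    estimates formation rates with a one-sided significance and linearity
    filter, performs nonparametric depth and treatment comparisons
    (Kruskal-Wallis, pairwise one-sided Wilcoxon with Benjamini-Hochberg
    adjustment), couples methane formation to primary production through
    Redfield C:P stoichiometry, handles nutrient bookkeeping with
    detection-limit censoring, normalizes phnJ marker-gene counts to the
    single-copy gene recA and to TPM, and ships a seeded synthetic-data
    generator emulating the full shipboard campaign so every stage is
    testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
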