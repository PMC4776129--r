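Package: metcrit
Title: Screening-Level Water Quality Criteria for Metals from
    Physicochemical Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating physicochemical descriptors of metal ions to
    regulatory acute water quality criteria (criteria maximum concentrations,
    CMCs). Screens descriptor tables against ln-transformed CMCs by Pearson
    correlation, builds an integrated-radius principal-component regression
    from covalent radius, ionic radius and electron density, validates it by
    cross-validation and leverage-based applicability-domain analysis
    (Williams plot), and predicts screening-level CMCs with confidence bands
    for metals lacking toxicity data. Ships the eight-metal USEPA training
    table and an amphipod LC50 comparison table as plain-text fixtures, plus
    a synthetic-table generator with planted effects for property testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
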