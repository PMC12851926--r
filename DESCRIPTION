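Package: agstrand
Title: Stranded Agricultural Assets Under Dietary Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An asset-extended physical multi-regional input-output (MRIO)
    pipeline for quantifying stranded farm capital under dietary change.
    Farm-type fixed-asset accounts (buildings, machinery and equipment,
    breeding livestock, land) are allocated to food commodities through a
    concordance matrix and output shares, embodied along supply chains with
    a Leontief contribution analysis, and shocked with isocaloric
    EAT-Lancet-style diet scenarios (moderate, low and zero animal-sourced
    food). The package reports stranded value and new-asset requirements by
    asset class and value chain, straight-line and declining-balance
    depreciation pathways, accelerated phase-out residuals, and
    inflation-adjusted historical sensitivity intervals. A seeded synthetic
    generator emulates FABIO-like balanced physical MRIO tables and
    FADN-like farm asset accounts so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
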