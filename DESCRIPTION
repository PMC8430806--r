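Package: ashbalance
Title: Mineralogical Mass Balance for Biomass Ash
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts Rietveld-quantified crystalline phase fractions of a
    biomass ash into per-element budgets via chemical-formula stoichiometry,
    derives the elemental composition of the amorphous phase by difference
    from bulk chemical analysis with Gaussian error propagation, and computes
    agronomic indices (water-soluble nutrient fractions of the crystalline
    assemblage, straw-to-ash element recovery). Includes a synthetic-sample
    generator for parameter-recovery and interval-coverage experiments, TSV
    readers and writers for phase and bulk tables, and a bundled reference
    dataset of four sorghum straw ashes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
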