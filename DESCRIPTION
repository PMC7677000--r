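Package: symbioscreen
Title: Screening Bacterium-Derived Metabolites That Protect Insect Larvae
    from Fungal Infection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An untargeted LC-MS screening workflow for identifying
    bacterium-derived metabolites that mediate colonization resistance of
    onion maggot (Delia antiqua) larvae against the entomopathogenic fungus
    Beauveria bassiana. Covers QC-based feature filtering, from-scratch
    PLS-DA with VIP scores and a permutation overfitting diagnostic, a
    two-step fold-change cascade against a medium blank and a
    non-protective control strain, ppm-tolerance compound annotation with
    nutrient exclusion, in-situ body-surface concentration estimation from
    pooled larval washes, protective-cocktail formulation with a serial
    dose design, bioassay summarization with a normality/homogeneity
    test-selection tree, and Kaplan-Meier/log-rank survival analysis.
    Synthetic-data generators emulate every input so the full pipeline is
    testable without the original deposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    car,
    nortest,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
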