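Package: hemosurf
Title: Cerebral Haemodynamic Patterns, Misery Perfusion and Response Surface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies cerebral oxygen extraction fraction (OEF) from
    TRUST-MRI T2 decay series and global cerebral blood flow (CBF) from
    phase-contrast velocity maps, builds neuropsychological Z-score
    composites and vascular-risk variables for an ageing cohort,
    classifies joint OEF/CBF quadrants (including the misery-perfusion
    phenotype), fits covariate-adjusted association models and MANCOVA,
    and performs second-order response surface analysis with
    balance-axis and bias-axis inference. A synthetic-cohort generator
    reproduces the statistical structure the analysis assumes so the
    whole pipeline is testable without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    tibble
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
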