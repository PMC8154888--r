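Package: swimherit
Title: Quantitative Genetics of Critical Swimming Speed in Nile Tilapia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives critical swimming speed (Ucrit), surface area and daily
    growth coefficient phenotypes from incremental-velocity swim challenge
    tests and grow-out records of Nile tilapia; builds pedigree numerator
    relationship matrices and inbreeding coefficients; and estimates variance
    components, heritabilities and genetic correlations with univariate and
    bivariate REML animal models fitted through sparse mixed-model equations.
    Includes a full-sib/half-sib breeding-design simulator for parameter
    recovery studies and an analysis pipeline producing publication-style
    tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
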