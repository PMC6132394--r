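Package: d9assess
Title: Contaminant Trend and Compliance Assessment for Seafood Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing contaminants in fish and shellfish under the
    Marine Strategy Framework Directive Descriptor 9 (contaminants in seafood).
    Aggregates censored dioxin/furan/dl-PCB congener panels into WHO toxic
    equivalents under upper/middle/lower-bound conventions, performs wet/dry/
    lipid basis and breathing-water matrix corrections, checks compliance
    against food maximum levels, biota environmental quality standards and
    OSPAR environmental assessment criteria, and assesses temporal trends with
    a fixed-window LOESS smoother, ANOVA decomposition into linear and
    non-linear components (Fryer-Nicholson), and contrast tests between time
    points. Includes a seeded generator of synthetic annual pooled monitoring
    series with lognormal noise and left-censoring at a limit of
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
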