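Package: lactotran
Title: Translational Pharmacokinetic-Pharmacodynamic Modeling of Prolactin
    Response to Dopamine D2 Antagonists
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semimechanistic prolactin turnover models for dopamine D2
    receptor antagonists: a precursor-pool model with drug-stimulated
    release from a lactotroph pool, and an agonist-antagonist interaction
    model with a hypothetical dopamine feedback loop.  Includes competitive
    receptor-occupancy algebra, allometric rat-to-human translation of
    turnover rate constants, analytic two-compartment intravenous and
    sequential zero-/first-order oral absorption pharmacokinetics, a
    dose-regimen simulation engine, a synthetic rat-study generator, and
    maximum-likelihood recovery of pharmacodynamic parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
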