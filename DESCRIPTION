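Package: nose2brain
Title: Formulation Optimization and Nose-to-Brain Targeting Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for intranasal nanoparticle
    formulation studies: three-factor Box-Behnken designs with coded/actual
    unit mapping, transformed polynomial response-surface models with the
    full diagnostic panel (Type III ANOVA, lack-of-fit against pure error,
    PRESS-based predicted R-squared, adequate precision), Derringer
    desirability multi-response optimization, Franz-cell release and
    permeation parameters (steady-state flux, apparent permeability,
    sampling-replacement correction), and non-compartmental
    pharmacokinetics with nose-to-brain targeting statistics (brain/blood
    AUC ratios, drug targeting efficiency DTE, direct transport
    percentage DTP). Includes closed-form simulators for design-of-
    experiments responses, two-compartment intranasal/intravenous
    concentration profiles, and diffusion-cell runs with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
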