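Package: svagree
Title: Repeated-Measures Agreement Between Pulse-Wave-Analysis and
    Doppler Ultrasound Stroke Volume
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for method-comparison studies of beat-to-beat stroke
    volume monitors under lower body negative pressure (LBNP) with
    isometric handgrip (IHG). Provides a synthetic beat-level cohort
    generator with the full LBNP/IHG protocol structure, trimmed 30-second
    aggregation with protocol-driven exclusions, derived hemodynamic
    variables (cardiac output, systemic vascular resistance, body surface
    area), and a repeated-measures Bland-Altman framework based on linear
    mixed models: variance-component limits of agreement, within-subject
    limits of agreement and percentage error, covariate-dependent bias
    (mean of methods, systemic vascular resistance, sex interaction,
    time-during-handgrip proxy), and per-method precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
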