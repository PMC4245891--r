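Package: eicorrect
Title: Population-Level Correction of Self-Reported Dietary Energy Intake
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing and correcting misreporting in self-reported
    24-hour dietary recall of total energy intake at the population level.
    Implements Schofield resting metabolic rate prediction, physiological
    plausibility bounds on the energy-intake index (EI/RMR), a linear
    regression model of percent misreporting with backward stepwise
    refitting, a rank-alignment "intake shift" correction based on per-sex
    log-normal physical activity level distributions, Monte-Carlo survey
    population simulation with age-sex stratified resampling, and synthetic
    data generators emulating doubly-labeled-water validation cohorts and
    national survey populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
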