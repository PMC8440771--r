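Package: drowsydrive
Title: Unmasking Latent Sleepiness During Supervised Automated Driving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for paired-drive studies of
    driver sleepiness under manually controlled versus self-driving
    (supervised automation) conditions. Generates ground-truth-annotated
    synthetic EEG/EOG recordings and behavioral outcomes; preprocesses EEG
    with mastoid re-referencing, a zero-phase filter chain, and automated
    excision of ocular artifacts from the EOG product signal; detects slow
    rolling eye movements (SREMs) and builds time-to-first-SREM survival
    records; estimates Welch power spectra and band-specific envelope
    synchronization via the binarized derivative method (BDM); summarizes
    psychomotor vigilance task (PVT), Karolinska Sleepiness Scale (KSS),
    and actigraphy-derived sleep history; and runs the full repeated-
    measures statistical battery (negative binomial count models with
    cluster-robust inference, stratified log-rank tests, Wilcoxon
    signed-rank, random-intercept mixed models, paired t-tests, adjusted
    Hedge's g, and a priori sample-size calculation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    lme4,
    lmerTest,
    sandwich,
    signal,
    stats,
    survival,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
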