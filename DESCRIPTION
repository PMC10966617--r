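Package: postictalr
Title: Postictal EEG Restoration and Clinical Reorientation After
    ECT-Induced Seizures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies restoration of cortical activity after
    electroconvulsive-therapy (ECT) induced seizures from continuous
    peri-ictal EEG, and relates it to the clinical recovery of
    orientation in person, place, and time. The postictal EEG is
    band-pass filtered, epoched, artifact-screened, and summarised as a
    per-minute normalized alpha-delta ratio (ADR) computed from Welch
    power spectral densities. The ADR trajectory is fitted with a
    lag-parameterised sigmoidal recovery model from which the amplitude
    of recovery, the initial lag, the time constant, and the moment of
    fastest restoration (T_max) are extracted. Reorientation times are
    scored per cognitive domain from question logs, and per-domain
    linear mixed models with by-subject random intercepts and T_max
    slopes relate clinical reorientation to the EEG features and
    treatment covariates. A synthetic-data generator with analytic
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
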