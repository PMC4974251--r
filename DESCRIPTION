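Package: gonogoerp
Title: Simulation and Analysis of Response-Related ERPs in a Cued Go/Nogo Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for event-related potential (ERP) studies of
    motor preparation in a cued go/nogo paradigm with a within-subject
    stimulation (active/sham) crossover. Simulates trial-level multi-channel
    EEG with known component parameters (contingent negative variation,
    target-locked P300, lateralized motor potentials, ex-Gaussian response
    times), reads and writes continuous recordings (EDF) with event streams,
    implements the standard signal chain (average-mastoid re-referencing,
    zero-phase band-pass and notch filtering, epoching, baseline correction,
    amplitude-threshold artifact rejection, condition averaging), quantifies
    CNV mean amplitude, P300 peak measures and lateralized readiness
    potential (LRP) onset latencies by 25% fractional-area latency, and runs
    the corresponding inference layer: repeated-measures/mixed ANOVA and
    default-prior (JZS) Bayes-factor model selection over the factorial
    design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
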