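Package: gonogoeeg
Title: Error-Processing EEG and Post-Error Behavior in Go/No-Go Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of error monitoring in go/no-go EEG
    experiments: behavioral post-error adjustments (post-error slowing and
    accuracy with RT-matched post-correct controls, response-stimulus
    intervals, tertile analyses), response-locked event-related potentials
    (error-related negativity at a frontal F3/F4 region of interest), and
    frontal theta (4-7 Hz) event-related spectral perturbations computed
    with a 1 Hz Hilbert filter bank and decibel baseline normalization on
    trial-average power. Inference uses sample-wise paired sign-flip
    permutation t-tests with a consecutive-sample criterion, rank tests,
    one-way ANOVA on waveform areas, r effect sizes and Bonferroni control.
    Includes a fully parameterized synthetic cohort generator (task
    sequences, reaction-time dynamics with configurable post-error effects,
    14-channel 128 Hz EEG with phase-locked and induced components, blink
    artifacts) so the whole pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    signal,
    pracma,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
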