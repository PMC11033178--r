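Package: lickphase
Title: Lick-Cycle Phase Locking and Event Modulation Analysis for Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-unit recordings made during reward
    consumption. Builds event-aligned peri-stimulus time histograms with
    baseline z-scoring and causal half-normal smoothing, classifies per-unit
    event modulation with paired Wilcoxon tests, segments licks into bouts
    and lick cycles, assigns spike phases on the lick cycle and tests phase
    locking with circular statistics (Rayleigh, V, two-sample Kuiper,
    binomial proportion z), quantifies lick microstructure and fluid intake,
    and simulates the closed-loop self-administration task
    (cumulative-presence pump rule, lick-triggered excitation and inhibition
    trains). A seeded synthetic-session generator with inhomogeneous-Poisson,
    von Mises phase-locked spiking provides ground-truth inputs so every
    stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
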