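Package: skatephase
Title: Temporal Events, Inner-Cycle Phases and Sub-Technique Detection for
    Ski Skating from Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pole and ski ground-contact events (initial and final
    contact) in cross-country roller-ski skating from wrist- and ski-mounted
    inertial measurement units, alongside a marker-based reference detector
    operating on vertical marker trajectories. Assembles per-limb events into
    skiing cycles, computes inner-cycle temporal parameters (pole/ski contact
    and swing times, cycle time, pole-ski delays), classifies the G2/G3/G4
    skating sub-techniques with a decision tree, and quantifies method
    agreement with intra-trial bias/precision, inter-trial median/IQR
    summaries, Kruskal-Wallis omnibus tests and Dwass-Steel-Critchlow-Fligner
    pairwise post-hoc comparisons. Ships a synthetic trial generator with
    ground-truth events so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
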