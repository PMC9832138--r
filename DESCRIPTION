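Package: inhibmotifs
Title: Choice-Selective Inhibition in Attractor Models of Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how the specificity of inhibitory connections
    shapes winner-take-all decision dynamics in cortical circuit models. Implements
    a reduced two-variable mean-field model of two competing excitatory populations
    with parameterised excitatory-excitatory, excitatory-inhibitory and
    inhibitory-excitatory connection specificity, a four-variable extension with
    explicit choice-selective inhibitory populations, fixed-point and bifurcation
    analysis (stability classification, slow saddle time constants, specificity-space
    scans), behavioural task simulation (psychometric, chronometric and trial-completion
    curves, working-memory persistence, inhibitory perturbation experiments), and a
    Dale-constrained excitatory-inhibitory recurrent network trained by
    backpropagation through time, with ROC-based choice-selectivity analysis and
    connection-specificity estimation from trained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
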