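Package: mirrorpop
Title: Population Analyses of Motor Cortical Activity During Grasp
    Execution, Observation, and Withholding
Version: 0.1.0
Authors@R:
    person("Mirrorpop", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-level analysis of motor cortical
    (M1/F5) spiking activity recorded during a Go/NoGo reach-to-grasp
    task performed, observed, and withheld. Provides multi-event aligned,
    soft-normalized population rate tensors, mirror-neuron classification
    by two-way ANOVA, cross-condition epoch correlations with shuffle
    nulls, PCA subspace fitting with a variance-alignment index tested
    against random orthonormal nulls and neuron-subsample bootstraps,
    pseudo-population decoding with a maximum-correlation-coefficient
    classifier and consecutive-bin cluster significance, and EMG-based
    trial gating (envelope extraction, iterative contaminated-trial
    exclusion, median splits). Includes a seeded synthetic-session
    generator with planted latent subspaces for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
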