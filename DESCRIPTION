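Package: ecglv
Title: Emergent Coexistence in Generalized Lotka-Volterra Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of emergent coexistence in generalized
    Lotka-Volterra (GLV) communities with random pairwise interactions.
    Provides random and structured interaction-matrix ensembles, adaptive
    integration of GLV dynamics with an extinction threshold, algebraic
    sampling of feasible and linearly stable communities, detection of
    emergent coexistence (stable states harbouring pairs that cannot coexist
    in isolation) with analytic regime boundaries, collectivity and
    condition-number metrics of indirect effects (spectral radius, Neumann
    series, net-effect matrices, measurement-error and pairwise-assembly
    experiments), and intransitivity metrics (competitive ranks, low-rank
    exclusions, rock-paper-scissors triplets) with null expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
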