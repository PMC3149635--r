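Package: memrecon
Title: Attractor-Network Simulation of Memory Reconsolidation and
    Extinction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates contextual fear memory as attractors of a
    continuous-activation (0/1) Hopfield-style recurrent network.
    Two independent plasticity processes act after every session: a
    Hebbian learning term (HLP, scaled by a synthesis factor S) that
    strengthens connections among coactive neurons, and a
    mismatch-induced degradation term (MID, scaled by a degradation
    factor D) that weakens connections responsible for disagreement
    between the presented cue and the retrieved attractor.
    Nonreinforced reexposure of variable duration mixes the shock and
    non-shock context cues through a sigmoid, so that the same network
    exhibits simple retrieval, reconsolidation, or extinction depending
    on reexposure length, and pharmacological manipulations (protein
    synthesis inhibition S = 0, plasticity enhancement S > 0.8,
    degradation blockade D = 0) reproduce the corresponding behavioral
    phenomenology. Includes protocol presets, freezing readouts over
    replicate simulations, parameter sweeps, Lyapunov energy landscapes
    projected by multiple discriminant analysis, and storage-capacity
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
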