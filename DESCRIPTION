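Package: tiltBMI
Title: Simulation and Analysis of PSTH-Template Brain-Machine Interface
    Learning Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse tilt brain-machine interface (BMI)
    experiments in which four platform-tilt types are decoded from cortical
    spike trains with a peri-stimulus time histogram (PSTH) template
    classifier. Provides an inhomogeneous-Poisson spike-train simulator with
    ground-truth tuning trajectories for learner, nonlearner and control
    cohorts; online (previous-day templates) and offline (leave-one-out)
    minimum-Euclidean-distance decoding; shuffle-bias-corrected mutual
    information from confusion matrices, spike-timing versus spike-count
    information, and ensemble redundancy; single-neuron response metrics
    (responsiveness, peak response, peak latency, normalized variance);
    and session-level learning measures (performance normalization,
    learner classification, naive-versus-expert PSTH distances, intertrial
    cumulative-sum fits), tied together by a reproducible pipeline with
    tidy CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'specs.R'
    'simulate.R'
    'psth.R'
    'decode.R'
    'info.R'
    'response.R'
    'learning.R'
    'io.R'
    'pipeline.R'
    'utils.R'
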