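Package: vnsim
Title: Simulation and Analysis of Vagus Nerve Stimulation Effects on Heart
    Rate and Laryngeal Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to construct temporally patterned vagus nerve stimulation
    (VNS) pulse trains, synthesize trial recordings (ECG and laryngeal EMG)
    with known ground truth, and quantify heart-rate and evoked-EMG responses.
    Includes a stochastic model of VNS-evoked bradycardia in which a
    frequency-filtering vagal-to-ganglion synapse gates acetylcholine release
    onto a gap-junction-coupled sinoatrial pacemaker network, a Ding-type
    force-fatigue model of laryngeal muscle activation fitted by a
    neighborhood particle swarm optimizer, a simplified myelinated-fiber
    recruitment model, and sum-of-squares effect-size analysis of the
    stimulation parameter space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
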