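Package: timernet
Title: Columnar Spiking-Network Model of Interval Timing with Simulated
    Optogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a modular columnar spiking network in which
    recurrently connected excitatory Timer cells learn to span temporal
    intervals, inhibitory interneurons gate a population of Messenger cells
    whose firing-rate peak reports the stored time, and an eligibility-trace
    reinforcement rule stores intervals and sequences in the synaptic weight
    matrix.  Inhibitory cells carry a simulated optogenetic current so that
    disinhibition and excess inhibition can be imposed during training or
    recall.  Includes a readout stage (population rates, report times,
    epileptic/flat/misordered trial classification, functional-range and
    sweep summaries, two-way ANOVA of train-by-test conditions), declarative
    experiment protocols, and synthetic rate-trace fixtures for testing the
    readout in isolation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
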