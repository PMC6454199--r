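Package: snncomm
Title: Communication-Efficient Distributed Spiking Neural Network Simulation at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study interprocess communication in distributed
    time-step spiking neural network (SNN) simulations without a cluster.
    Generates layered cortical-microcircuit-style and modular multi-area
    benchmark networks, models spike communication as a hypergraph (one
    hyperedge per presynaptic neuron and its postsynaptic targets), and
    allocates neurons to processes by round robin, balanced random
    assignment, or multilevel hypergraph partitioning (agglomerative
    inner-product matching, Fiduccia-Mattheyses refinement) under a load
    imbalance constraint. A leaky integrate-and-fire simulator runs over
    virtual processes so that spike dynamics are bit-identical across
    allocations while per-step communication is accounted message by
    message under two census exchange patterns: personalized exchange
    (PEX, explicit all-to-all handshake) and dynamic sparse neighborhood
    exchange (NBX, asynchronous barrier). Hardware-independent metrics
    (average runtime neighbors, remote spikes, handshake and payload
    volume) support strong-scaling comparison experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
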