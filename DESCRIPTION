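Package: liquidstate
Title: Liquid State Machines with Leaky Integrate-and-Fire Reservoirs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and training of Liquid State Machines: discrete-time
    leaky integrate-and-fire spiking networks with a frozen random recurrent
    reservoir and a readout layer trained by spatio-temporal backpropagation
    on a spike-rate loss. Includes reading and writing of binary
    address-event-representation (AER) streams in the N-MNIST dialect,
    binning of event streams into spike rasters, a seeded generator of
    synthetic labelled event streams, uniform weight quantization of the
    reservoir, and both batch and streaming inference, the latter with a
    rhythmic inhibitory reset pulse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
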