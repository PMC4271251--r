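Package: fhnmem
Title: Self-Sustained Memory Patterns in Loop-Plus-Branch FitzHugh-Nagumo Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a small loop-plus-branch network of excitable
    FitzHugh-Nagumo neurons coupled by delayed dual-exponential chemical
    synapses with a heterogeneous baseline conductance, stimulated through a
    single sensory node. Provides the stimulus protocol, a fixed-step
    compiled integrator with an event queue for the synaptic delay,
    spike-raster observables (inter-spike intervals, phase-locking profile,
    pattern period, spikes per period, short- vs long-term-memory
    classification, wavefront collision localisation), closed-form nullcline
    and excitability theory (knee points, firing window, maximal baseline
    conductance, stimulus feasibility), and parameter-sweep drivers for the
    stimulus and topology parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
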