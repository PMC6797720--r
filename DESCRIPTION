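Package: chipCA
Title: Cellular Automata for Collective Cell Behaviour in Microfluidic
    Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bounded-lattice cellular-automata simulation of collective
    cell growth, stochastic newborn death, invasion and drug response
    inside lab- and organ-on-a-chip geometries. Simulation domains are
    derived from black/white device masks (or generated synthetically
    for a set of canonical microfluidic layouts), cell proliferation
    follows von Neumann neighbourhood growth with per-species iteration
    schedules, and a calibration module maps observed growth curves
    (day, mean cell count) to the per-interval iteration counts that
    reproduce them.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    png,
    yaml,
    igraph,
    digest
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    tiff,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
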