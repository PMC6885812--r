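Package: calosc
Title: Calcium Oscillation Detection and Network Activity Analysis for
    Neuron-Glial Cultures
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing spontaneous calcium activity in primary
    neuron-glial cultures imaged with a fluorescent calcium indicator,
    together with the companion assays used in neuroprotection studies.
    Implements a derivative-threshold oscillation detector for per-cell
    fluorescence traces, network activity summaries (percentage of working
    cells, oscillation frequency and duration), raster diagrams and
    network-synchrony calling, mitochondrial respirometry state summaries
    and the respiratory control index, relative gene-expression analysis by
    the delta-delta-Ct method, two-channel nucleus-counting viability
    ratios, and one-way ANOVA with Dunnett many-to-one post hoc
    comparisons. A seeded synthetic-data generator produces fluorescence
    recordings, respirometry tables and qPCR Ct tables with known ground
    truth so the whole pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
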