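Package: dendrodyn
Title: Dendrite Branch Dynamics from Traced Neuron Skeleton Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the dynamics of developing dendritic arbors from time
    series of traced neuron skeletons (SWC). Partitions dendritic mass into
    four directional sectors (dorsolateral, dorsomedial, ventromedial,
    ventrolateral) around an olfactory-neuropil coordinate frame; detects
    bulk extension and retraction events on long-cadence recordings; extracts,
    tracks and classifies terminal branches (stable, transient, emerging,
    retracting) with signed tip speeds on short-cadence recordings; segments
    recordings into initial, transitional and final targeting phases; and
    ships a seeded birth-death skeleton simulator with full ground truth so
    every stage of the pipeline can be validated without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
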