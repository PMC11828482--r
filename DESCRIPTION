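Package: azquant
Title: Quantification of Calcium-Channel Active-Zone Imaging and Synaptic Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification pipeline for presynaptic
    calcium-channel imaging and electrophysiology at the Drosophila larval
    neuromuscular junction. Implements single-molecule photobleaching
    channel counting (penalized change-point step fitting, unitary-intensity
    estimation), Costes-threshold Pearson/Manders colocalization within a
    membrane mask, active-zone puncta detection with nearest-punctum
    distance and masked-intensity quantification, and evoked-transmission
    metrics (Gaussian low-pass filtering, EPSC amplitude/half-width/charge,
    paired-pulse ratios, synaptic-depression fits, mean quantal content).
    Seeded synthetic-data generators with ground-truth sidecars make every
    stage testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
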