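Package: meaburst
Title: Network Burst, Superburst and Propagation-Motif Analysis for
    Microelectrode Array Recordings
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and characterization of rhythmic population activity in
    multielectrode-array (MEA) recordings of cultured neuronal networks.
    Implements median-based threshold spike detection, network-burst detection
    from the binned total spiking rate, superburst detection by Gaussian-kernel
    correlation, first-spike activation patterns and activation-timing gradient
    (dynamic pattern) vector fields, motif clustering of burst patterns with
    Davies-Bouldin cluster-number selection, and superburst typing with
    motif-fidelity and switching statistics. A ground-truthed synthetic MEA
    generator reproduces the assumed statistical structure (planar-wave small
    bursts at theta-range interburst frequencies nested in long superbursts) so
    that every stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    signal,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'circular.R'
    'io.R'
    'layout.R'
    'meaburst-package.R'
    'motifs.R'
    'patterns.R'
    'pipeline.R'
    'raw-signal.R'
    'sequence-stats.R'
    'spike-detection.R'
    'superbursts.R'
    'synthetic.R'
    'tsr-bursts.R'
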