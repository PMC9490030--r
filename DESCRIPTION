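Package: collidr
Title: Spike-Collision Testing for Antidromic Identification of Neuronal Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying neuronal projections from multichannel
    extracellular (tetrode) recordings by the spike-collision test. Implements
    real-time-style high-pass filtering and spike detection, two protocols for
    inferring antidromic spikes evoked by site-specific (optogenetic)
    stimulation, an emulator of the closed-loop spike-triggered stimulation
    controller, and the offline judgment of collision tests via ROC analysis of
    spike elimination and latency-jitter criteria. A ground-truth simulator of
    axonal collision and refractory physics generates labelled synthetic
    recordings so the whole pipeline can be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
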