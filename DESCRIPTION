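Package: synaptiq
Title: Quantal Analysis of Synaptic Vesicle Release from Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of glutamatergic synaptic transmission in whole-cell
    voltage-clamp recordings: template-matched miniature EPSC detection with
    negative-control false-positive correction, readily releasable pool (RRP)
    estimation from hypertonic-sucrose responses and from cumulative charge of
    high-frequency stimulus trains, EPSC deconvolution to vesicle release-rate
    waveforms, vesicular release probability, pool replenishment rates,
    first-order rate constants for spontaneous, asynchronous and evoked
    release, Hill fits of the calcium dependence of evoked release, and
    current-clamp membrane metrics.  Includes a stochastic quantal-synapse
    simulator that produces recordings with known ground truth so every
    estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
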