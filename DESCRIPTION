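Package: okrcircuit
Title: Optokinetic Reflex Gain, Cortical Direction Tuning, and Feedforward
    Drive onto the Accessory Optic System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studies of the visual-cortex to
    NOT-DTN (nucleus of the optic tract / dorsal terminal nucleus)
    pathway that drives the horizontal optokinetic reflex (OKR).
    Implements eye-trace desaccading and Fourier-amplitude OKR gain,
    cortical-contribution and potentiation metrics, direction and
    orientation tuning analysis for two-photon calcium and extracellular
    spiking data (vector-sum preferred direction, OSI/DSI, responsiveness
    and outlier rules, calcium deconvolution, antidromic latency and
    jitter), pre/post plasticity indices, population bias randomization
    tests and cell-density grids, and a firing-rate feedforward model
    that converts cortical population tuning and plasticity into synaptic
    charge onto a brainstem target. A synthetic-data module generates
    eye traces, tuned calcium and spiking populations, and spatial cell
    maps with known ground truth so every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
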