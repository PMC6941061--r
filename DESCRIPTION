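Package: rcmo2
Title: Tick-Based Simulation of Oxygen Dynamics in the Rat Renal Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic, tick-based simulator of oxygen delivery,
    diffusion and consumption in an idealized 320 x 320 x 10 micrometre
    slab of rat kidney cortex. The tissue is a 32 x 32 lattice of typed
    patches (peritubular capillary, tubular epithelium, tubule lumen,
    interstitium). Capillary and luminal convection renew oxygen each
    millisecond tick, hemoglobin binds and releases oxygen with
    saturation-dependent Hill kinetics, oxygen diffuses between adjacent
    patches by Fick's first law over effective exchange surfaces, and
    epithelial patches consume oxygen for housekeeping and for
    sodium-reabsorption work with Michaelis-Menten gating. Includes a
    deterministic tissue builder, the perfusion cascade from renal blood
    flow down to per-capillary and per-tubule flows, steady-state and
    ischemia/anoxemia protocols with half-time read-outs, local
    sensitivity analysis, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
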