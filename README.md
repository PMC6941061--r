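# rcmo2 — oxygen dynamics in the rat renal cortex at the cell-tissue level

The renal cortex is lavishly perfused yet extracts little oxygen, spends
most of what it takes on proximal sodium reabsorption, and decompensates
within seconds of ischemia. `rcmo2` is a deterministic, millisecond-tick
simulator of cortical oxygenation at the histological scale, for renal
physiologists and modellers who want a mechanistic, patch-resolved account
of where cortical oxygen comes from and where it goes — including the
often-ignored delivery of dissolved oxygen by the tubular fluid itself.

The model is an idealized 320 × 320 × 10 µm slab of rat cortex: a 32 × 32
lattice of 10-µm cubic patches typed as peritubular capillary (PTC),
tubular epithelium (EPI), tubule lumen (LUM) or interstitium (INT). Each
tick (default 1 ms) applies, in order:

1. **Convective renewal** — every PTC patch exchanges the volume fraction
   CFF = capFactor · CVF · Δt/(6·10⁻² V) against feed blood, every LUM
   patch the fraction TFF = TVF · Δt/(n_LUM · 6·10⁻² V) against fresh
   filtrate, with CVF and TVF derived from renal blood flow through the
   single-nephron perfusion cascade (SNGBF → SNEABF → SNGFR → SNAPR).
2. **Hemoglobin** — saturation-dependent kinetics with Hill index
   n(S) and pseudo-velocity k′c(S); dissociation k′c (αP₅₀)ⁿ S versus
   association k′c (αPO₂)ⁿ (100−S), four O₂ per tetramer, integrated
   implicitly per patch so that the stiff exchange with the small
   dissolved pool stays stable and exactly conservative.
3. **Diffusion** — Fick's first law on the lattice,
   J(i→j) = (1/L) D_ij S_ij [O₂]ᵢ, with pairwise effective exchange
   surfaces (brush border EPI–LUM 2000 µm², EPI–EPI 800, PTC–EPI 157,
   PTC–INT 39, default 100).
4. **Consumption** — Michaelis–Menten gated (Km = 1.1 µM): epithelial
   housekeeping (1.9 mM-EPI/min) plus the sodium-transport cost
   (1/3 ATP per Na⁺, P/O₂ ATP per O₂, transcellular fraction only,
   bicarbonate-coupled reabsorption oxygen-free), endothelial-crown
   consumption in capillaries, low interstitial housekeeping.

Two named parameter sets ship with the package: `rcm0`, the reference
configuration, and `rcmstar`, the physiologically adjusted one (tubule
length 12,400 µm, fractional reabsorption 0.75, transcellular fraction
0.56, bicarbonate factor 1.5, ATP/O₂ 5.5). Tissue grids are built
deterministically from a four-digit code (capillary/tubule ratio × 10,
outer tubule diameter): `"1540"` is the reference tissue.

## Worked example

```r
library(rcmo2)

p <- rcm_params("rcm0")          # reference constants
f <- compute_flow_cascade(p)     # perfusion cascade
f
#> <rcm_flows> RBF 5.3 FU
#>               value
#> CBF    4.770000e+00
#> OpNe   2.700000e+04
#> SNGBF  1.766667e+02
#> SNEABF 1.436300e+02
#> SNGFR  3.303667e+01
#> SNAPR  1.684870e+01
#> CVF    2.534239e+01
#> TVF    2.461232e+01
#> SNFLNa 4.691207e+09
#> wkGFR  8.919900e-01
```

SNGFR comes out at the textbook 33 nL/min; one capillary carries
25.3 nL/min, one tubule 24.6 nL/min. Build the reference tissue and run to
steady state (feeds 56/40 mmHg, RBF 5.3):

```r
g <- build_tissue("1540", p)
g
#> <rcm_tissue> spec 1540 (renal) - 32 x 32 patches
#>   counts: PTC 74  EPI 588  LUM 196  INT 166
#>   tubule fraction 0.766, capillary density 723 mm^-2, Nc/Nt 1.51

sim <- run_to_steady_state(rcm_sim(p, g))
round(sim$sst_po2, 1)            # volume-weighted mean tissue PO2, mmHg
#> [1] 39.8
round(c(PTC = mean_po2(sim, "PTC"), EPI = mean_po2(sim, "EPI"),
        LUM = mean_po2(sim, "LUM"), INT = mean_po2(sim, "INT")), 1)
#>  PTC  EPI  LUM  INT
#> 55.2 38.2 38.3 40.1
```

The capillaries sit within a mmHg of their feed (hemoglobin buffers them),
while the lumen-fed epithelium sets the tissue level. An ischemic
transient from the adjusted configuration:

```r
ps <- rcm_params("rcmstar")
gs <- build_tissue("1540", ps)
tr <- run_transient(ps, gs, rcm_protocol("ischemia"), horizon_ms = 9000)
tr
#> <rcm_transient> ischemia
#>   pre-switch: tissue=41.09  PTC=55.30  Hb_sat=74.77
#>   t50 (s):    tissue=2.38  PTC=5.08  Hb_sat=4.64
```

Tissue oxygen halves in ~2.4 s; the hemoglobin-buffered capillaries hold
out for ~5 s. Deactivate hemoglobin (`rcm_params("rcmstar", Hb_active =
FALSE)`) and the same half-times collapse to 0.40 s and 0.31 s — the bound
store is what makes renal ischemia a seconds-scale event. Other one-liners:
`hb_equilibrium_saturation(56, p)` gives 74.8% saturation at the capillary
feed; `apparent_capillary_velocity(f, p)` gives 5.4 mm/s (and motivates
the `capFactor` correction); `delta_hb(p, g)` gives the ~0.2 mmHg
steady-state hemoglobin contribution at reference flow, rising above
9 mmHg at 0.2 FU.

A command-line interface wraps the same functions:

```sh
Rscript inst/exec/rcm tissue build --spec 1540 -o tissue.map
Rscript inst/exec/rcm flows --preset rcm0 -o flows.csv
Rscript inst/exec/rcm run --preset rcmstar --tissue 1540 --rbf 5.3 \
        --ptc 56 --lum 40 --protocol ischemia -o ischemia_run
Rscript inst/exec/rcm hbcurve -o hbcurve.csv
```

Outputs are CSV time series (`time_ms, tPO2_mmHg, PTC_PO2_mmHg, ...`), a
TSV PO₂ snapshot matrix, and a JSON run manifest from which any run can be
reproduced bit-identically.

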