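---
title: "Oxygen dynamics in the rat renal cortex: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxygen dynamics in the rat renal cortex: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcmo2)
```

## The problem and the model

The renal cortex receives a luxurious blood supply yet extracts little of
the oxygen it is offered, and its oxygenation collapses quickly under
ischemia. Most of its oxygen is spent by the proximal tubular epithelium on
sodium reabsorption, which is itself proportional to glomerular filtration.
`rcmo2` simulates these couplings at the cell-tissue ("histological")
scale: an idealized 320 × 320 × 10 µm slab of cortex is discretized into a
32 × 32 lattice of 10-µm cubic patches of four types — peritubular
capillary (PTC), tubular epithelium (EPI), tubule lumen (LUM) and
interstitium (INT). Each patch holds an oxygen content $q$ (amol; with the
1000-µm³ patch volume, 1 amol corresponds to 1 µM, and PO₂ $= q/(\alpha V /
1000)$ with solubility $\alpha = 1.34$ µM/mmHg). The simulation advances in
fixed ticks (default 1 ms), applying four operators in order: convective
renewal, hemoglobin exchange, lattice diffusion, and consumption.

Inputs are renal blood flow (RBF, mL·min⁻¹·gkw⁻¹, "flow units") and the
capillary and luminal feed PO₂ (mmHg). The primary output is the
volume-weighted mean tissue PO₂, with per-compartment breakdowns.

## Perfusion cascade

Dependent flows derive algebraically from the independent parameters:

$$\mathrm{CBF} = \mathrm{RBF}\cdot f_{CBF}, \qquad
  \mathrm{SNGBF} = 10^6\,\mathrm{CBF}/\mathrm{OpNe},$$
$$\mathrm{SNEABF} = \mathrm{SNGBF}\,[1 - FF(1 - Hct)], \qquad
  \mathrm{SNGFR} = \mathrm{SNGBF} - \mathrm{SNEABF},$$
$$\mathrm{CVF} = \frac{\mathrm{SNEABF}}{f_{capBr}} +
  \frac{0.5\,\mathrm{SNAPR}}{f_{capBr}}, \qquad
  \mathrm{TVF} = \mathrm{SNGFR} - 0.5\,\mathrm{SNAPR},$$

with SNAPR $= fr_{PR}\cdot$SNGFR the absolute proximal reabsorption,
returned to the capillary side at tubule mid-length (hence the
half-weights). With the defaults (cortical fraction 0.90 and 27,000
operational nephrons per gram, chosen so that SNGFR = 33 nL/min, the
standard rat value) the cascade yields CVF ≈ 25.3 and TVF ≈ 24.6 nL/min.
Per tick, a capillary patch exchanges the fraction
$\mathrm{CFF} = f_{cap}\,\mathrm{CVF}\,\Delta t/(6\times10^{-2} V)$
(≈ 0.42 at reference flow; residence time ≈ 2.4 ms) of its volume against
feed blood, and each of the $n_{LUM}$ luminal patches of a tubule section
the fraction $\mathrm{TFF} = \mathrm{TVF}\,\Delta t/(n_{LUM}\, 6\times
10^{-2} V)$ against fresh filtrate. The capillary hemodynamic factor
$f_{cap}$ (default 1) rescales only the capillary renewal and the apparent
capillary velocity $v = f_{cap}\mathrm{CVF}/(6\times10^{-2}\pi R_c^2)$; it
exists because distributing the post-glomerular flow over six capillaries
overestimates measured capillary velocities several-fold.

Sodium reabsorption assigned to one epithelial patch is
$T_{Na} = fr_{PR}\cdot \mathrm{SNFLNa}\cdot (1/n_{EPI})\cdot
(10/L_{tub})$ amol/min, where $n_{EPI}$ is 12 (40-µm tubules) or 16
(50-µm) and the factor $10/L_{tub}$ takes the 10-µm slice of the full
tubule length.

## Hemoglobin

Capillary patches carry tetramer hemoglobin $Hb_t = [Hb]_{RBC}\cdot
Hct\cdot V/1000 = 2340$ amol homogenized over the patch, giving a blood
O₂ capacity of $4 Hb_t = 9360$ amol/patch ≈ 9.4 mM — the physiological
value, which is why the tetramer reading (with the factor 4 in the oxygen
balance) is the default; a monomer reading is selectable
(`hb_monomer = TRUE`) for comparison. Kinetics use a saturation-dependent
Hill index and pseudo-velocity scale

$$n_{Hill}(S) = \frac{2.635 S^2 - 274.042 S}{S^2 - 104.1 S - 31.32},
\qquad k'_c(S) = 6.325\, e^{2.88697 \cdot 0.011537\, S},$$

with dissociation and association percent-rates
$J^{\%}_{diss} = k'_c (\alpha P_{50})^{n} S$ and
$J^{\%}_{asso} = k'_c (\alpha \mathrm{PO_2})^{n} (100 - S)$ ($\alpha$ in
mM/mmHg inside the powers). The association rate acts on the *unsaturated*
fraction $(100 - S)$: only then is the fixed point the familiar sigmoid
curve with 50% saturation at $P_{50} = 36.8$ mmHg, which the model's own
reconstructed dissociation curve displays; a saturated-fraction variant is
kept behind `hb_literal_asso = TRUE` for comparison. The oxygen balance per
tick is $\Delta q = 4(J_{diss} - J_{asso})$ with $J = 0.01 J^{\%} Hb_t$.

**Numerical integration.** These percent-rates are of order 1 %/ms while a
capillary patch dissolves only ~75 amol at feed pressure; one percentage
point of saturation corresponds to ~94 amol. An explicit per-tick update of
the coupled (q, S) pair is therefore unconditionally unstable at any
practical tick (the fast eigenvalue of the linearized exchange is about
−7.6/ms). The package integrates the per-patch exchange implicitly:
backward Euler on (q, S) under the exchange invariant $q + 0.04\,Hb_t S$,
reduced to one monotone scalar equation per patch and solved by vectorized
bisection. The implicit update coincides with the explicit one when rates
are slow over a tick, conserves dissolved + bound oxygen to machine
precision, and behaves as a near-equilibrium hemoglobin buffer — which is
what gives ischemic relaxations their seconds-long half-times.

The equilibrium saturation solver (`hb_equilibrium_saturation()`) finds
the self-consistent fixed point $S = 100 r/(1+r)$,
$r = (\mathrm{PO_2}/P_{50})^{n_{Hill}(S)}$ by bisection to $10^{-6}$; it
initializes capillary saturation and supplies the saturation of inflowing
blood. The Hill-index endpoints are evaluated with $S$ clamped to
$[0.1, 99.9]$ to avoid zero-power pathologies. A three-parameter power-law
regression is sometimes substituted for $k'_c$ to save computation; it is
numerically incompatible with the exponential form (off by orders of
magnitude) and is not shipped.

## Diffusion

Fick's first law on the lattice: for each ordered neighbour pair, the
unidirectional flow is $J_{i\to j} = (1/L) D_{ij} S_{ij} [O_2]_i$ amol/ms
with $L = 10$ µm, $D_{ij}$ the mean diffusivity of the two patches and
$S_{ij}$ the pairwise effective exchange surface: 2000 µm² for EPI–LUM
(brush border), 800 for EPI–EPI, 157 for PTC–EPI (already including the
two-fold contact adjustment), 39 for PTC–INT, 100 otherwise. All flows are
computed synchronously from start-of-tick contents; for equal volumes the
unidirectional form is algebraically identical to a gradient-driven net
flux, and the update is one sparse matrix–vector product. At setup the
worst-case per-patch outflow fraction is checked against the tick and the
maximum admissible tick reported (the reference tissue is stable to ~1.2
ms; the default 1 ms tick passes, and halving it moves the steady state by
< 0.05 mmHg). Grid boundaries are closed (no-flux): the slab sits between
two cortical radial arteries and no boundary exchange is defined.

## Consumption

All consumption is Michaelis–Menten gated by $M = [O_2]/(K_m + [O_2])$
with $K_m = 1.1$ µM (cytochrome oxidase). Epithelial patches spend
$J_{HK} = 1.9$ mM-EPI/min of housekeeping plus the transport cost
$$J_{TNa} = \frac{1/3}{P/O_2}\cdot\frac{fr_{TC}}{f_{BIC}}\cdot T_{Na}
\cdot M,$$
i.e. one ATP per three pumped Na⁺, $P/O_2$ ATP per O₂, only the
transcellular fraction costs pump work, and bicarbonate-coupled
reabsorption proceeds at no oxygen cost (hence $f_{BIC}$ as a divisor; the
stoichiometry is stored as the integer 3-Na⁺-per-ATP rather than the
rounded 0.33). At reference settings this is ≈ 10.0 mM-EPI/min, well below
the ~26 mM-EPI/min Na⁺/K⁺-pump capacity equivalent. Capillary patches
consume through their endothelial crown: the endothelium-specific 1.2
mM/min is scaled by the crown volume fraction $\pi(R_c^2 - (R_c-h)^2)\cdot
10/1000 \approx 0.218$ at $h = 0.75$ µm (midpoint of the 0.5–1 µm range).
Interstitial patches default to 0.5 mM-INT/min, an order-of-magnitude
placeholder constrained to stay below 5% of total consumption. A step that
would overdraw a patch consumes exactly what is present (explicit anoxia
handling); contents never go negative.

When the run RBF changes mid-protocol (ischemia), the per-patch $T_{Na}$
is *held* at its pre-switch value by default: local reabsorption persists
for a while after filtration stops, and the no-hemoglobin ischemic
half-times are only reproduced under this convention. The literal
recoupling to the instantaneous SNGFR is available via
`tna_follows_flow = TRUE`.

## Tissue builder

Cell-automaton tissue maps are traditionally hand-edited in graphical
level editors, which makes them irreproducible; `rcmo2` instead uses a
deterministic constructive algorithm so that every grid is reproducible
from its code
("1540" = capillary/tubule ratio 1.5, outer tubule diameter 40 µm).
Tubule cross-sections are square blocks (4 × 4: 12 EPI ring + 4 LUM core;
5 × 5: 16 EPI + 9 LUM) on a fixed lattice — paired blocks separated by
1-patch interstitial corridors, 49 tubules at 40 µm (tubule volume
fraction 0.766) and 25 at 50 µm (0.610), both inside the morphometric
60–80% v/v range. Capillaries are placed singly by a row-major scan of
corridor patches, preferring sites adjacent to epithelium and not adjacent
to an already-placed capillary, until `round(ratio × n_tubules)` are
placed; the count is nudged minimally when needed to keep the areal
density inside 250–1110 mm⁻² (only the "1050" variant needs this, 25 → 26).
Structural invariants (section composition, LUM-only-next-to-LUM/EPI,
PTC-never-next-to-LUM, density and ratio bands) are checked on every
build. The muscle-oriented variant keeps the capillary bed, re-types every
LUM patch as EPI, gives all fibres one uniform consumption (default 3
mM/min, mid sub-maximal striated-muscle range) and has no tubular flow.

What the generated tissue emulates is the *aggregate* morphometry of the
cortex (patch-type fractions, capillary density, exchange surfaces); what
it does not emulate is the irregular geometry of the cortical labyrinth —
real capillary/tubule contact statistics, axial continuity of tubules, or
segmental (S1/S2/S3) heterogeneity. Results that depend only on aggregate
morphometry transfer to real tissue better than results that depend on
contact topology (see Limitations).

## Engine, protocols, read-outs

Steady-state runs start from an all-zero oxygen field with capillary
saturation at the feed equilibrium, and iterate until every compartment's
mean PO₂ moves less than 0.01 mmHg over a 100-ms window (a tolerance of
ours; stabilization is visible by ~500 ms) or 10,000 ticks elapse (then a
warning). Divergence (PO₂ > 200 mmHg) or invalid contents abort with the
offending patch. The intra-tick operator order (convection → hemoglobin →
diffusion → consumption) is not canonical; the operators are
near-commuting and swapping hemoglobin and consumption moves the steady
state by ~0.13 mmHg at a 1-ms tick and < 0.05 mmHg at 0.5 ms.

Protocols switch inputs at a given time from the established steady state:
ischemia sets RBF = 0 (both convections stop), anoxemia zeroes both feed
PO₂ while flow continues. Half-times $t_{50}$ are the first times a
monitored series (tissue PO₂, capillary PO₂, saturation) falls to half its
*pre-switch* value, linearly interpolated between 10-ms samples; times to
10% are recorded alongside. A patch-clamping utility holds selected
patches at fixed PO₂ (for high-PO₂-source experiments); clamped patches
are excluded from budget-closure accounting.

Every run is deterministic: identical inputs give bit-identical monitor
output; there is no randomness anywhere in the package.

## Sensitivity and verification analyses

`rsc()` computes the relative sensitivity of steady-state tissue PO₂ by
central difference, $[\,\mathrm{sst}(p+\Delta p) -
\mathrm{sst}(p-\Delta p)\,]/\mathrm{sst}(p) \,/\, (2\Delta p/p)$ with
$\Delta p = 0.2\,p$ by default. The propagated parameter error is half the output spread
across ±1 SD of the parameter; fraction-valued parameters are clamped to
[0, 1]. The SD table marks entries whose SDs are not anchored in the main
analysis as provisional. Morphometric parameters (capillary/tubule ratio,
tubule diameter) are probed by switching tissue variants, not by scalar
perturbation. `io_slopes()` gives d(sstPO₂)/d(feed) by central difference
around the reference feeds (±4 mmHg); `delta_hb()` is the difference of
two steady states with hemoglobin active versus deactivated;
`verify_flows()` ratios the simulated flow cascade against a packaged
reference table whose unanchored entries are marked provisional.

## Problem sizes and runtime

All shipped analyses are desk-scale: a steady state is 900–2,000 ticks
over 1,024 patches (≈ 1–3 s); an ischemic transient runs 9 s of simulated
time (9,000 ticks, ≈ 25 s); the acceptance script completes in well under
a minute and the full test suite in a few minutes on one CPU.

## Known limitations

* **Contact topology.** The regular block lattice yields stronger
  capillary–epithelium and interstitial coupling than the irregular
  cortical labyrinth; combined with the large brush-border exchange
  surface this pins the epithelium close to the lumen and the steady-state
  tissue PO₂ a few mmHg above reported in-vivo cortical values, whose
  compartment gradients presuppose weaker coupling. Input–response *slopes* are robust
  to this; absolute levels carry the offset.
* **Accessible hemoglobin store.** With near-equilibrium hemoglobin
  exchange, blood oxygen content (~9.4 mM) keeps delivery far above
  consumption even at very low flow, so the steady state does not collapse
  until extreme ischemia; the seconds-long ischemic half-times require
  exactly this accessibility. A kinetically locked store would give the
  opposite trade-off.
* 2D slab, no axial gradients, no pressure-driven/resistive flows, no
  tubular compliance or collapse, no renal or systemic regulation, no
  erythrocyte discreteness, no Bohr-effect modulation of $P_{50}$, no ATP
  pool or metabolic regulation; minutes-to-hours phenomena are out of
  scope.
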