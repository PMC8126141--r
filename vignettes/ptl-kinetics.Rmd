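---
title: "Modeling the cellular response to plasma-treated liquid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the cellular response to plasma-treated liquid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptlkin)
```

## The model

Plasma-treated liquids (PTLs) kill cells mainly through their long-lived
reactive species, dominated by hydrogen peroxide and nitrite. `ptlkin`
models a single cell in such a liquid as two well-mixed compartments —
extracellular (EC) and intracellular (IC) — coupled only by first-order
membrane diffusion with a linear concentration gradient (Fick's law):
for each membrane-permeant species $i$, the flux term
$-k_{D,i}(c_i^{EC} - c_i^{IC})$ enters the EC rate equation and its
negation enters the IC equation. H2O2, ONOO$^-$, NO2$^-$ and ONOOH
diffuse; the enzyme states, H$^+$ and CO2 do not. Both compartments are
treated with equal effective volume, so the flux magnitudes are
identical on both sides.

The reaction network comprises:

* the two-step catalase cycle (IC only):
  CATFeIII + H2O2 $\xrightarrow{k_1}$ compound I, and
  compound I + H2O2 $\xrightarrow{k_2}$ CATFeIII + O2, with
  $k_1 = 1.7\times10^7$, $k_2 = 2.6\times10^7$ M$^{-1}$s$^{-1}$
  (mammalian catalases). The two states always sum to the initial
  catalase concentration — an exact conservation law used as a solver
  check;
* peroxynitrous acid formation (both compartments):
  NO2$^-$ + H2O2 + H$^+$ $\xrightarrow{k_3}$ ONOOH,
  $k_3 = 1.1\times10^3$ M$^{-2}$s$^{-1}$ (third order);
* the ONOOH/ONOO$^-$ acid–base pair, with recombination
  $k_{-4} = 10^{10}$ M$^{-1}$s$^{-1}$ and dissociation
  $k_4 = 10^{-\mathrm{p}K_a} k_{-4}$. The literature p$K_a$ range is
  6.5–6.8; the package defaults to 6.8 and exposes it as a parameter —
  the headline results move only a few percent across the range;
* catalase-mediated ONOO$^-$ decomposition (IC only, regenerating
  NO2$^-$), $k_5 = 1.7\times10^6$ M$^{-1}$s$^{-1}$;
* the CO2-catalyzed ONOO$^-$ sink, $k_6 = 5.8\times10^4$
  M$^{-1}$s$^{-1}$, whose product ONOOCOO$^-$ is not itself reactive in
  this network. The package accumulates it per compartment in `sink_ec`
  / `sink_ic` purely as bookkeeping, so that total nitrogen
  (ONOO$^-$ + NO2$^-$ + ONOOH + sinks) is conserved and testable;
* constant mitochondrial H2O2 production in the IC,
  $k_P = 10^{-7}$ M s$^{-1}$.

H$^+$ and CO2 are dynamic state variables with their own rate equations;
no buffering or clamping is imposed. In practice their excursions are
negligible at the default doses, but keeping them dynamic preserves the
printed structure of the equations.

A *cell phenotype* is the pair (`kd1`, `cat0`): the H2O2 membrane
diffusion rate constant (a stand-in for aquaporin expression,
100–2000 s$^{-1}$, reference 920 s$^{-1}$) and the intracellular
catalase concentration (10$^{-8}$–10$^{-5}$ M). Cancer-like cells sit at
high `kd1` / low `cat0`, normal-like cells at the opposite corner. A
*treatment scenario* is the initial extracellular (H2O2, NO2$^-$) dose;
the four canonical regimes cross 1 µM / 1 mM H2O2 with 0 / 1 mM
nitrite.

## Initialization

Before treatment the intracellular H2O2 is assumed stationary: constant
production $k_P$ balanced by catalase (all in the CATFeIII form) and the
nitrite pathway,

$$c_{1,ss}^{IC} = \frac{k_P}{k_1\,\mathrm{CAT}_0 + k_3 c_5^{IC} c_6^{IC}}.$$

`steady_state_h2o2()` implements this closed form, and `initial_state()`
uses it for the IC H2O2 at $t = 0$ (with compound I, ONOO$^-$ and ONOOH
zero, IC NO2$^-$ at $10^{-4}$ M, H$^+$ at $10^{-7}$ M and CO2 at
$10^{-3}$ M in both compartments). Two caveats are worth stating. First,
the formula assumes compound I is exactly zero at steady state, which is
not the kinetic steady state of the two-state catalase cycle; it is a
consistent *initialization convention* rather than a true fixed point of
the full system, and the early transient relaxes the small discrepancy
within milliseconds. Second, because $k_1 \mathrm{CAT}_0$ dominates the
denominator everywhere in the sweep range, the baseline IC H2O2 spans
$\sim 10^{-7}$ M (at $\mathrm{CAT}_0 = 10^{-8}$ M) down to
$\sim 10^{-10}$ M (at $10^{-5}$ M).

## Numerics

The system is stiff: time scales range from the sub-microsecond
ONOO$^-$/ONOOH protonation equilibrium to the ~100 s decay of the
extracellular pool. `simulate_cell()` integrates with `deSolve`'s
`lsoda` (adaptive, switching to BDF on stiffness), with dense output
interpolated onto a three-phase grid: spacing $10^{-7}$ s up to 10 ms,
$10^{-5}$ s up to 1 s, $10^{-3}$ s up to the fixed horizon of 100 s
(~3×10⁵ samples). Internal steps are adaptive and independent of the
output grid. There is no event handling, steady-state detection or
adaptive horizon.

Tolerances default to `rtol = 1e-8` and `atol = 1e-22`. The absolute
tolerance deserves a comment: intracellular ONOO$^-$ peaks at only
$10^{-17}$–$10^{-16}$ M in the selective regime, so an `atol` anywhere
near the superficially "safe" $10^{-14}$ M leaves those components
uncontrolled and their temporal maxima dominated by integration noise —
enough to scramble the nitrite-synergy fold entirely. With
`atol = 1e-22` every dynamically relevant component is resolved, at a
negligible cost (the solver takes ~10⁴ steps per run either way). The
governing contract, enforced by tests, is grid-refinement stability:
every measure changes by less than 0.5 % when all output spacings are
halved and when both tolerances are tightened tenfold.

For sweeps, `sweep_time_grid()` widens each output spacing tenfold
(~3×10⁴ samples). The same 0.5 % stability contract is checked against
the full grid; measures, not samples, are the product.

Verification is two-route: `reference_integrate()` is a deliberately
naive fixed-step 4th-order Runge–Kutta integrator over the same
right-hand side, stable on short horizons at `dt_fixed = 1e-9` s. The
test suite requires the stiff solution and the oracle to agree to a
normalized discrepancy below $10^{-5}$ per species over the first
$10^{-4}$ s at three phenotype/scenario corners; in practice they agree
to ~$10^{-12}$. The oracle is also checked against a closed-form
exponential-decay subsystem.

## The susceptibility measures

From each trajectory `compute_measures()` derives:

* `c1_max`, `c4_max` — temporal maxima of IC H2O2 and ONOO$^-$, with a
  parabola through the three samples bracketing the discrete argmax
  (ties resolve to the earliest time);
* `tau` — the time for IC H2O2 to return within a 10 % band above its
  pre-treatment baseline: the *last* downward crossing of
  $1.1 \times$ baseline, linearly interpolated; 0 if the band is never
  left, the horizon if never re-entered. The band-above-baseline
  semantics follows the stated tolerance-of-increase definition; a
  literal band-below-baseline variant (`rule = "literal"`) is provided
  for comparison. Whether the first or last crossing is meant is
  genuinely open; the last crossing ("return to tolerance") is the
  package's reading;
* `l1`, `l4` — trapezoidal time-integrals of the IC concentrations over
  the full horizon, and `l1_bs`, the signed integral above a baseline
  (by convention the steady-state IC H2O2 of the most resistant
  phenotype, catalase $10^{-5}$ M, i.e. $5.88\times10^{-10}$ M);
  negative excursions are not clipped;
* `r_bar`, `r_max` — the average (by the fundamental theorem,
  $|c_1^{EC}(t_f) - c_1^{EC}(0)|/t_f$) and maximal instantaneous
  magnitude of the extracellular H2O2 consumption rate, and their
  inverses `s_bar`, `s_max` (reported as `NA`, not infinity, for a zero
  rate). Magnitudes are used throughout: the raw average rate is
  negative since H2O2 is consumed, and a signed "susceptibility" would
  be meaningless.

## Sweeps and summary ratios

`run_sweep()` evaluates all measures over a (kd1, cat0) grid — default
100×100, linear on both axes, with logarithmic spacing available per
axis — for any set of scenarios, recomputing the steady-state
initialization per catalase value. Execution order is deterministic,
failed points are recorded rather than dropped, and an optional
checkpoint file makes long sweeps resumable.

Three summaries condense a surface:

* `selectivity_ratio()` — the measure at the most susceptible corner
  (max kd1, min cat0) over the most resistant corner (min kd1, max
  cat0). In the selective regime `c1_max` gives ≈ 3.6, the
  ~four-fold separation between cancer-like and normal-like phenotypes.
  At low catalase the kd1-dependence is negligible, so the susceptible
  corner's kd1 choice barely matters;
* `synergy_ratio()` — per-point folds of a measure between matched
  with-/without-nitrite sweeps plus median/min/max. The ONOO$^-$ peak
  rises about an order of magnitude (median ≈ 11) when 1 mM nitrite
  accompanies 1 µM H2O2, while `c1_max` stays within a few per mill —
  nitrite synergy acts through peroxynitrite, not through the H2O2 peak
  itself, in this network;
* `kd1_dependence_profile()` — the relative spread of a measure across
  the kd1 axis per catalase value, which locates the shift (around
  catalase $\sim 10^{-7}$ M) between the catalase-dominated and
  diffusion-limited regimes without hard-coding it.

## Problem sizes and design choices

The package's own test and reproduction workloads use 10×10 grids for
the regime bounds and the corner ratio, and 5×5 paired grids for the
synergy folds, all on the sweep output grid; corner-point summaries are
spacing-independent by construction, and corner measures from coarse
and dense grids agree exactly (same inputs, same solver). These sizes
resolve every reported quantity well inside its tolerance — the
surfaces are smooth and monotone in both axes — while keeping a full
reproduction to a few minutes of computation.

Other choices made where the design was genuinely open:

* equal effective compartment volumes (fluxes enter both compartments
  with equal magnitude), matching the printed structure of the rate
  equations; a volume ratio would scale the IC flux terms;
* no lumping of the catalase cycle: the full two-step cycle is
  integrated even though $k_1 \approx k_2$ would permit a one-constant
  approximation;
* ONOOCOO$^-$ is a terminal sink, not a species; the radical
  decomposition channel (CO3$^{\bullet-}$/$^{\bullet}$NO2 and their
  reaction with catalase) is deliberately out of scope;
* `kd1` is static — no aquaporin gating dynamics, no effect of the
  treatment itself on membrane permeability;
* no temperature or pH dependence of the rate constants beyond the
  literature values, and no cell-death threshold layer: the package
  reports measures, not viability.

## Limitations

The model is a two-compartment caricature: no spatial gradients within
compartments, no membrane-proximal depletion layers, no peroxiredoxin /
glutathione scavenging (catalase is the only H2O2 sink beside the
nitrite pathway), constant mitochondrial production, and phenotypes
reduced to exactly two numbers. The conservation-law and
refinement-stability tests validate the numerics, not the biology:
agreement there shows the equations are solved correctly, not that the
network suffices to describe any particular cell line. Measured rate
constants were obtained under conditions (pH, temperature) that differ
from a treated cell, so all absolute concentrations should be read as
order-of-magnitude statements.

## A worked run

```{r, eval = FALSE}
ph <- cell_phenotype(kd1 = 2000, cat0 = 1e-8)   # cancer-like
sc <- treatment_scenario("selective_nonsynergistic")
tr <- simulate_cell(ph, sc, grid = sweep_time_grid())
compute_measures(tr)
```

The peak IC H2O2 for this phenotype is ~7.9×10⁻⁷ M, reached a few
milliseconds after treatment; the most resistant phenotype
(`kd1 = 100`, `cat0 = 1e-5`) peaks at ~2.2×10⁻⁷ M, the ≈3.6-fold
separation that motivates `c1_max` as a susceptibility measure.
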