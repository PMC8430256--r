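---
title: "Models and methods: single-cell electromechanics and conductance maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: single-cell electromechanics and conductance maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cardioEMD asks a single question of a single cardiac cell: when the maximum
conductances of its ten sarcolemmal channels are reduced, which reductions
delay the *onset of contraction* relative to the *onset of excitation* —
the electromechanical delay (EMD)? The package answers it with a
two-model pipeline (ventricular electrophysiology feeding a myofilament
contraction model), a factorial population sweep over conductance
scalings, scalar biomarker extraction, and a dimensional-stacking
visualization whose axis ordering is optimized to expose the dominant
channels. This vignette documents the models, the parameter choices the
package had to make where its source models were silent or inconsistent, the
numerical schemes, and the limitations of each.

## The electrophysiology model

The cell model is the ten Tusscher–Panfilov human ventricular myocyte
(2006 formulation): Hodgkin–Huxley currents I_Na, I_CaL, I_to, I_Kr,
I_Ks, I_K1, I_pK, I_pCa, I_bNa, I_bCa plus the Na/Ca exchanger and Na/K
pump, three calcium compartments (cytosol, SR, diadic subspace), and a
four-state Markov ryanodine receptor reduced to one ODE by tracking the
aggregate Rbar = R + O:

* dRbar/dt = −k2·CaSS·Rbar + k4·(1 − Rbar), with k1 and k2 modulated by
  SR load through kcasr = maxsr − (maxsr − minsr)/(1 + (EC/CaSR)²);
* O = k1·CaSS²·Rbar/(k3 + k1·CaSS²), I_rel = V_rel·O·(CaSR − CaSS).

Compartment volumes (V_c = 16.404, V_SR = 1.094, V_SS = 0.05468 μm³),
F = 96.4867 C/mmol and all current formulations are the source model's;
`epParameters()` exposes them. A *conductance scaling* is a vector of ten
positive multipliers applied to the maximum conductances (never to
gating kinetics, and never to the exchanger or pump); the population
sweep draws each multiplier from {0.25, 0.50, 0.75, 1.00}.

### Protocol, cell type and initial conditions

The paced protocol stimulates with −52 pA/pF for 1 ms at the start of
each cycle, runs 50 beats at a fixed basic cycle length (600 or 1000 ms),
and returns the final beat sampled at 1 ms. Two protocol details are not
derivable from the source models and were fixed against the analysis's
calibration anchors — a normal-case (all-100%) last-beat peak Cai of
1.247 μM at BCL 600 ms and 0.889 μM at BCL 1000 ms:

* **Transmural cell type.** The package defaults to the endocardial
  parameter set (`epi`/`M` selectable via `epConfig(cell_type=)`). With
  the default initial state below, the endocardial cell matches both
  anchors within ~3% (1.262 and 0.861 μM), whereas the epicardial set
  overshoots both by ~6%; the anchors are the only available evidence
  about this otherwise free choice.
* **Initial state.** `epInitialState("protocol")` uses the model
  family's published initial values (Nai = 11.6, Ki = 138.3 mM,
  Cai = 0.2 μM, CaSR = 0.2 mM). Starting instead from the quiescent rest
  of the calcium-dynamics variant (Nai = 7.67 mM) leaves intracellular
  sodium — whose relaxation time is minutes — far from its paced steady
  state after 50 beats and depresses the calcium transient by 8–14%.
  The quiescent state remains available as `epInitialState("rest")` and
  is the reference for stimulus-free stability checks.

### Numerical scheme

Operator splitting with Rush–Larsen exponential updates for the twelve
Hodgkin–Huxley gates and explicit Euler for V, the ion concentrations
and Rbar, at an internal step of 0.02 ms. Halving the step moves the
normal-case APD90 by well under 1 ms (asserted in the test suite). The
L-type driving term uses an `expm1` formulation with a series limit at
V = 15 mV to avoid the removable singularity. Any non-finite state
aborts the case and flags the record as diverged rather than crashing a
sweep.

## The myofilament model

Contraction follows the Rice et al. (2008) lumped crossbridge model,
driven one-way by the electrophysiology beat's Cai(t) (linearly
interpolated; no feedback of force or length on the ionic model — the
printed mechanical equations consume only calcium). Its stages:

1. **Calcium–troponin binding** to a high- and a low-affinity population
   (k_on = 50 μM⁻¹s⁻¹, k_offH = 25 s⁻¹, k_offL = 250 s⁻¹).
2. **Regulatory activation**: the overlap-weighted bound fraction
   Trop_Regulatory gates the non-permissive ↔ permissive transition
   through permtot = sqrt(1/(1 + (perm50/Trop_Regulatory)^n_perm)) with
   perm50 = 0.5 and n_perm = 15, the inverse capped at 100.
3. **Crossbridge cycling** through the four-state chain N ↔ P ↔ XB_PreR
   ↔ XB_PostR with temperature- and strain-modulated rates, plus the
   parallel two-state no-crossbridge pair.
4. **Mean distortions** of the strongly bound states, combining
   crossbridge turnover (normalized by the duty fractions) with the
   ½·dSL/dt filament-sliding advection.
5. **Force balance and length dynamics**: normalized active force
   (single-overlap scaled, normalized by the maximal post-rotation duty
   fraction), titin/collagen passive force, a series-elastic afterload
   KSE·(SL − SL0), and sarcomere-length evolution through the
   viscosity/mass form dSL/dt = (Integral_Force + (SL0 − SL)·visc)/mass.

Three places required a decision where circulated descriptions of the
model are internally inconsistent:

* **Regulatory base rates.** The regulatory rates are sometimes listed
  as k_n−p = 50 s⁻¹ and k_p−n = 500 s⁻¹, yet the force normalization is
  defined in the fully activated limit k_n−pT ≫ k_p−nT. Since
  permtot ≤ 1 scales k_n−pT *down* and the capped inverse scales k_p−nT
  *up*, that limit is unreachable under the first assignment; the
  package uses k_n−p = 500 s⁻¹, k_p−n = 50 s⁻¹, which honors the
  normalization limit and still deactivates fully at resting calcium.
* **Sign of the force integral.** Written with a tension-positive
  integrand (F_active + F_passive − F_preload − F_afterload with
  F_afterload = KSE·(SL−SL0)), the length ODE would make active force
  *lengthen* the cell. The dynamics integrate the balance in the
  shortening direction instead (`totalForce()$F_contraction`), so the
  series-elastic equilibrium is KSE·(SL0 − SL) = F_active and the
  activated cell shortens. The tension-positive form is still exposed
  as `F_integrand`.
* **Temperature exponent.** Both Q10 factors use (TmpC − 37)/10 (a
  common transcription drops the /10 from one of them); at the 37 °C
  default every Q10 factor is exactly 1.

### Numerical scheme and stability

With the source model's mass (5·10⁻⁵) and viscosity (3·10⁻³), the
linear (SL, Integral_Force) pair is a stiff damped oscillator with
eigenvalues ≈ −30 ± 138i ms⁻¹ — outside the explicit-Euler stability
region at any practical step. The kernel therefore advances that 2×2
linear subsystem by backward Euler in closed form and everything
nonlinear (binding, occupancies, distortions) by explicit Euler at
0.002 ms. The resulting twitch is step-size converged: peak tension and
minimum length agree to <0.1% between dt = 0.002 and 0.001 ms (asserted
in the tests). Occupancy updates are written in flux form so both
regulatory pools conserve their sums to machine precision per step.
Mechanics start from rest and are pre-equilibrated for 2 s at the
trace's initial calcium before the beat, so normalized length starts at
exactly 1.

### The tension scale and the contraction criteria

A case *contracts* when its physical tension reaches the 20 kPa
"weight" and its normalized length falls to ≤ 99% of rest; the onset of
shortening is the interpolated 99% crossing, and
EMD = onset of shortening − onset of excitation (V crossing −40 mV).
The contraction model produces *normalized* force; the conversion to
kPa (`Tmax`) is a free constant. The package calibrates it once, to 300 kPa per
unit normalized force, the value at which the two unambiguous anchors
hold simultaneously: the all-100% configuration lifts the 20 kPa weight
at both pacing rates (25 and 74 kPa peak tension), and the 25%-CaL
region stays far below it (<0.1 kPa). This is a pipeline calibration
absorbing an unstated unit conversion, not a claim about maximal
myocardial tension.

A consequence worth stating plainly: with the published troponin
affinities and the steep n_perm = 15 activation, the force collapses by
orders of magnitude once the calcium transient peaks below ~0.6 μM.
Configurations whose transients sit near that cliff — intermediate CaL
with reduced calcium background — are exactly the long-EMD and
no-contraction cases, which is the qualitative structure this analysis
is designed to expose. It also means the no-contraction *boundary* (and
with it any EMD ceiling) depends directly on the tension calibration: a
configuration with peak Cai below ~0.5 μM cannot lift a physically
scaled 20 kPa weight in this model, so EMD magnitudes from differently
calibrated pipelines are comparable only qualitatively.

## Biomarkers

All extracted from the final beat, with linear interpolation at every
threshold crossing (1 ms output grid): APD90 (maximum-upstroke instant
to the first downward crossing of V_rest + 0.1·amplitude, V_rest taken
pre-stimulus; a beat that never repolarizes reports the beat length,
flagged), peak and resting Cai (resting = last sample), Cai duration
(width of the 90%-window above peak − 0.9·(peak − rest)), and Cai
upstroke slope. The slope definition admits more than one reading; the
package implements the mean upstroke gradient, 0.9·(peak − rest)
divided by the time from the 10%-rise crossing to the peak, and
isolates it in `caiAttributes()` so an alternative reading can be
swapped in one place. APD90's reference conventions (upstroke-anchored,
pre-stimulus rest) are likewise isolated in `apd90()`. No-contraction
records store missing sentinels (`NA`) for onset and EMD, never zeros.

## The population sweep

`enumerateScalings()` enumerates the factorial population (4^10 =
1,048,576 cases for all ten channels; tests and examples use sub-sweeps)
in a fixed mixed-radix order: the canonical channel ordering (Na, CaL,
to, Kr, Ks, K1, pK, pCa, bNa, bCa) with the first channel as the least
significant digit. `runSweep()` executes cases independently (any
execution order yields the same sorted table), appends each record to a
checkpoint CSV, and on restart skips completed (case, BCL) keys. The
per-case runner is injectable; the analytic surrogate (below) plugs in
through the same interface, which is how the sweep and stacking
machinery is tested without ODE cost.

## Dimensional stacking

A stacking layout splits the swept channels into an ordered x-axis and
y-axis list; each axis nests its channels outermost → innermost, the
outermost being the most significant base-4 digit (so its label spans
1/4 of the axis, the next channel 1/4 of that, and so on). The map for
the full population is 1024 × 1024; every factorial case occupies
exactly one cell. The roughness cost is the sum of |difference| over
all horizontally and vertically adjacent cell pairs, each counted once,
borders truncated, and pairs involving a missing-sentinel cell
contributing zero (an explicit choice: a missing cell has no natural
numeric stand-in, and exclusion avoids inventing one; a fixed-penalty
alternative would only re-rank layouts whose boundaries cross the
no-contraction region). Minimizing the cost assigns low-influence
channels to the short inner labels, so the dominant channel ends up
with the longest label — which is what makes the optimal map readable
at a glance.

`optimizeLayout()` searches layouts exhaustively when the count (modulo
the x/y swap symmetry, which provably leaves the cost unchanged) is
within a cap of 10,080 — i.e. through 8 channels — and otherwise by
seeded pairwise-swap hill climbing with restarts. For ≤ 4 channels the
heuristic recovers the exhaustive optimum across 20 seeds in the test
suite; for the full 10-channel problem (10!/2 ≈ 1.8 million layouts on
a 1024² map) a global search is cluster-scale and the heuristic is the
default. Ties break lexicographically, so results are deterministic.

## The analytic surrogate

`surrogateSpec()` defines closed-form biomarker responses with the
qualitative structure of the real sweep — APD rising with CaL and
falling with Ks/Kr/K1 (with a CaL×Ks interaction), peak Cai rising with
CaL/bCa and falling with Ks/Kr, EMD maximal at intermediate CaL levels,
no contraction at 25% CaL when bCa is low, plus optional seeded Gaussian
noise (default amplitude 0, making records pure functions of levels and
BCL). Effect magnitudes are chosen to span realistic dynamic ranges
(APD to ~560 ms, EMD to ~82 ms, peak Cai to ~3 μM) so downstream color
scales and binning are exercised; they are test fixtures, not
physiological claims, and the surrogate emulates no trace-level
dynamics — tests that pass on it validate the sweep/stacking machinery,
not the biology.

## Problem sizes and verification

The test suite and the acceptance script run desk-scale versions of the
full design: the two 50-beat normal-case runs, selected single cases,
a 256-case CaL × Ks × Kr × K1 factorial at BCL 600 ms
(the four APD-dominant channels), and 4-channel surrogate problems for
the stacking optimizer. These sizes keep a full run in minutes on one
core while still covering every code path of the full design; the full
2 × 4^10 sweep is supported by the same functions (checkpointed,
resumable) but is a cluster-scale computation.

Verification is layered: closed-form fixed points and steady states
(RyR, troponin, duty fractions), reference integrations with `deSolve`
and matrix exponentials as independent oracles for single steps,
conservation and boundedness properties over full runs, determinism and
step-halving convergence, and the calibration anchors described
above. Every number quoted in this vignette is computed by the test
suite or by `scripts/acceptance.R`.

## Known limitations

* Single cell only: no tissue coupling, no mechanical loading, so the
  EMD here is the intrinsic excitation–activation latency, not the
  loading-dependent delay of an intact ventricle.
* The mechanical calcium-sensitivity cliff makes the no-contraction
  boundary — and therefore EMD ceilings — sensitive to the tension
  calibration; EMD magnitudes are comparable across pipelines only
  qualitatively (see the tension-scale section).
* The two fixed pacing rates are the whole rate protocol; no
  restitution or premature-stimulus analysis.
* Biomarker conventions (APD90 reference, Cai slope) follow one
  explicit reading of ambiguous definitions, isolated for swapping.
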