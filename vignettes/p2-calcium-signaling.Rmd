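---
title: "Modeling P2Y2/P2X7-driven calcium signaling in osteoblasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling P2Y2/P2X7-driven calcium signaling in osteoblasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(P2CaSim)
```

## The biological problem

Osteoblasts sense extracellular ATP over six orders of magnitude of
concentration through two very different purinergic receptors: the
high-affinity G-protein-coupled receptor P2Y2, which drives IP~3~
production and calcium release from the endoplasmic reticulum (ER), and
the low-affinity ATP-gated cation channel P2X7, which admits calcium
across the plasma membrane. Their interaction produces a characteristic
dose dependence of the cytosolic calcium response: single transients at
low ATP, oscillations (periods of roughly 10–20 s) at micromolar ATP, and
wide transients again at millimolar ATP, with a non-monotonic magnitude
profile showing troughs near 10^−4^ and 10^−2^ M and a global maximum
near 10^−3^ M. P2CaSim implements a deterministic whole-cell model of this
system and the analysis pipeline around it: protocol simulation, knockout
variants, dose-response sweeps, slow-fast (Hopf) analysis, trace
featurization, and synthetic single-cell population generation.

## The model

Two well-mixed compartments, cytosol and ER, exchange calcium through six
fluxes (all in µM/s, referenced to cytosolic volume):

$$\frac{d[\mathrm{Ca}^{2+}]_i}{dt} = f_c\,(J_{INleak} + J_{P2X7} - J_{PMCA}
  + J_{IP3R} + J_{ERleak} - J_{SERCA})$$
$$\frac{d[\mathrm{Ca}^{2+}]_{ER}}{dt} = f_{ER}\,\gamma\,(J_{SERCA}
  - J_{IP3R} - J_{ERleak})$$
$$\frac{d[\mathrm{IP_3}]}{dt} = \alpha_{ATP}\,\frac{[\mathrm{ATP}]}
  {[\mathrm{ATP}]+k_{ATP}} - \delta\,[\mathrm{IP_3}]$$

where $f_c < f_{ER} \ll 1$ are free-calcium fractions (buffering) and
$\gamma$ is the cytosol:ER volume ratio. The pumps are Hill functions
$J_x = v_x\,c^2/(c^2+k_x^2)$ (PMCA extrusion, SERCA reuptake); the ER leak
is linear in the gradient; the plasma-membrane inward leak is constant.

IP~3~ receptor release follows the two-variable Li-Rinzel reduction of the
De Young–Keizer model: $J_{IP3R} = v_{IP3R}\,m_\infty^3 n_\infty^3 h^3\,
([\mathrm{Ca}]_{ER} - [\mathrm{Ca}]_i)$, with instantaneous activation by
IP~3~ ($m_\infty$) and calcium ($n_\infty$), and slow calcium-dependent
inactivation $h$. Activation and inactivation by cytosolic calcium make
the open probability biphasic — the core of calcium-induced calcium
release (CICR) and of the oscillatory regime.

P2X7 gating is a 12-state Markov scheme: three rows (naive, sensitized,
desensitized) of four states each, representing 0–3 occupied ATP binding
sites; channels open with two or more sites occupied (states Q1/Q2 naive,
Q3/Q4 sensitized, all with conductance $g_{X7}$). The whole-cell calcium
flux is the calcium-carried fraction of the open-channel current,
$J_{P2X7} = -f_{Ca}\, g_{X7} \Sigma Q \,(V_m - E)/(zFV_{cell})$, about
55 µM/s at full opening under the defaults.

Knockout variants follow the flux-zeroing convention: the P2Y2 knockout
zeroes $J_{IP3R}$ (IP~3~ dynamics remain), the P2X7 knockout zeroes
$J_{P2X7}$ (gating states still evolve).

## Parameter interpretation notes

Two entries of the published parameter table are dimensionally ambiguous
and are resolved as follows (both resolutions are exposed as options):

* **IP~3~ turnover rates.** The balance equation is implemented with a
  maximal production rate `alpha_ATP` = 0.03 µM/s and a degradation rate
  `delta` = 0.01 /s, the values the parameter table assigns to production
  and degradation respectively.
* **`g_X7` units.** The tabulated conductance is read as a whole-cell
  conductance of 2.5 × 10⁻⁸ S (25 nS). This is the only reading that makes
  the current equation dimensionally consistent and yields a physiological
  maximal flux (≈55 µM/s) after the current-to-flux conversion. Setting
  `g_X7_raw_units = TRUE` keeps the literal reading instead.

## Reconstructing the Markov wiring

The published rate table fixes the transition *rates* but not every
*arrow*, so the topology was reconstructed and validated against the
model's own dose-response surface (the package's acceptance checks). The
default wiring is:

* Naive row C1⇄C2⇄Q1⇄Q2 binds at `k2`, `k4`, `k6` × [ATP] and unbinds at
  `k1`, `k3`, `k5`; the sensitized row C3⇄C4⇄Q3⇄Q4 binds at `k7` × [ATP]
  on every step with the same unbinding ladder; the desensitized row
  mirrors the sensitized ladder (disable with
  `desensitized_ladder = FALSE`).
* Desensitization leaves the naive row with occupancy-dependent rates
  `H2_C2 < H2_Q1 < H2_Q2`; the desensitized row recovers to its naive
  counterpart at `H1`.
* Sensitization likewise accelerates with occupancy: slow (`L1`) from the
  partially bound states C2 and Q1, fast (`L3`) from the fully bound open
  state Q2; every sensitized state recovers at `L2`.
* Statistical multiplicity factors (3,2,1 binding / 1,2,3 unbinding) are
  available via `use_multiplicity = TRUE`, default off: the table lists
  single rates per transition class.

Among the twelve wirings examined, only this one simultaneously
reproduces the non-monotonic wild-type dose-response geometry (global
maximum near 10^−3^ M only modestly above the P2X7-knockout plateau,
troughs near 10^−4^ and 10^−2^ M), the monotone P2X7-knockout curve, and
a naive-start P2X7 submodel plateau near 40% of the wild-type maximum.

One caveat is inherited from the source parameter set: the tabulated
sensitized-row binding rate `k7` = 316 M⁻¹s⁻¹ is *smaller* than the naive
binding rates, although a higher sensitized open probability — and a
sensitized dose-response that saturates by 10^−2^ M — requires it to be
larger. With the tabulated value the sensitized-pool (C4-start) curve is
still rising at 10^−2^ M and reaches roughly 86% of the wild-type maximum
over the top quarter-decade (~120% at 10^−2^ M itself) rather than
plateauing near 200%. The sensitized plateau is, by construction, the one
output directly controlled by `k7`; users exploring that regime can raise
`k7` through `model_params()`.

## Numerical choices

* **Integration.** `deSolve::ode` with `lsoda` (stiff-capable), relative
  tolerance 10⁻⁸ and absolute tolerance 10⁻¹⁰; during the first 10 s after
  the ATP step the maximal step is capped at 0.05 s to resolve sub-second
  channel transients that set the early flux diagnostics. Output grid
  0.1 s (supports period estimation down to ~5 s).
* **Equilibration.** 2000 s at zero ATP from a generic physiological
  state, followed by refinement against the closed-form fixed point
  ($J_{INleak} = J_{PMCA}$; $J_{SERCA} = J_{ERleak}$; IP₃ = 0;
  $h = h_\infty$). The refinement matters because the ER compartment has a
  relaxation mode with a ~30 min time constant near rest, so finite-time
  integration alone cannot reach a residual below 10⁻⁶ µM/s. Resting
  cytosolic calcium under the defaults is 0.0319 µM.
* **Sensitized initial pool.** The sensitized closed state C4 has outflow
  at zero ATP (unbinding and slow recovery), so an equilibrated cell
  cannot *rest* in C4; the C4 pool is an onset initial condition imposed
  at stimulus time, representing receptors pre-sensitized by prior ATP
  exposure.
* **Probability conservation.** All 12 Markov fractions are integrated
  (no elimination); the sum is monitored and output states renormalized
  only if drift exceeds 10⁻⁷ (typical drift is below 10⁻⁹).
* **Dose sweeps.** 25 points/decade over 10⁻⁸–10⁻² M (151 stiff solves,
  about half a minute on one CPU); equilibration is shared across doses.
* **Extremum detection.** On the raw grid after a 3-point moving median —
  no spline smoothing, so extrema cannot be displaced by fitting. Flat
  runs are compressed; a terminal grid point lower than its neighbor
  counts as a trough only if an interior maximum precedes it, so a curve
  that has turned down after its peak registers a trough at the end of the
  sweep while a monotone curve registers none.

## Slow-fast analysis

IP~3~ and ER calcium vary slowly relative to cytosolic calcium and the
IP~3~R gate, so the P2Y2-only submodel ($J_{P2X7}=0$) is analyzed as a 2-D
fast subsystem with the slow variables frozen as parameters. At a fixed
point $h = h_\infty(\mathrm{Ca})$, which reduces the equilibrium problem
to one dimension; roots are located by sign-change scanning with
warm-started continuation along the ER-load axis and refined by Brent's
method. Stability comes from the eigenvalues of the finite-difference 2×2
Jacobian; the oscillatory region is where a complex pair has positive real
part, and its boundary (the Hopf curve) is extracted as the zero contour
of the real part restricted to complex pairs. The default window spans
IP₃ from 0 to the saturating steady state $\alpha_{ATP}/\delta$ = 3 µM and
ER loads from rest down to 10% of rest; the window and the 10 s
dwell/transit threshold are choices exposed in the API.

Trajectories of the full model are projected onto this plane and labeled
by total time spent inside the region: `outside`, `transits` (< 10 s) or
`dwells`. One limitation is worth knowing: because IP₃ production
saturates at micromolar ATP ($k_{ATP}$ = 1 µM), the slow-variable
trajectories at 10⁻⁵ and 10⁻³ M converge to nearly the same late state
and both re-enter the low-ER foot of the region late in a 120 s window;
the mid-dose trajectory dwells longest, and the high-dose crossing of the
region during the response phase is much briefer (≈2 s vs ≈7 s), but the
*total* dwell at high dose remains above the 10 s transit threshold.

## Trace featurization

Features are operational definitions, each threshold exposed as an
argument: baseline = pre-onset mean; magnitude = post-onset maximum −
baseline; activation time = first crossing of baseline + 10% of magnitude;
peaks = local maxima of a lightly smoothed trace (3-sample moving average)
with topographic prominence ≥ 2.5% of magnitude; oscillatory = at least
two peaks after the primary one; period = median inter-peak interval. The
2.5% prominence default reflects the physics of damped calcium oscillation
trains, whose successive peaks roughly halve in amplitude, so a genuine
third peak carries a prominence of a few percent of the primary transient;
at the same time 2.5% of a typical response sits more than 20 noise
standard deviations above the 2%-of-baseline measurement noise used in the
synthetic populations. A cell is non-responding when its magnitude is
below five pre-onset noise standard deviations (the expected maximum of
roughly a thousand baseline noise samples is ~3.3 SD).

## Synthetic populations

`generate_population()` emulates the heterogeneity structure of
single-cell Fura2 recordings with no access to raw data: lognormal
cell-to-cell multipliers (unit median, CV 0.2 by default) on pump and
receptor densities (`v_PMCA`, `v_SERCA`, `v_IP3R`, `g_X7`) and on the
initial ER load; a Bernoulli mixture of naive (C1) and sensitized (C4)
receptor pools with weight `p_sensitized`; additive i.i.d. Gaussian
measurement noise (default SD 2% of the resting signal); and an optional
log-dose axis shift per simulated cell line. Everything is reproducible
from the recorded seed. The lognormal choice is a modeling default —
expression-level variation is multiplicative and positive — not an
estimate; CV = 0.2 is a typical protein-expression variability scale.

What the generator deliberately does **not** emulate: photobleaching or
baseline drift, indicator saturation and calibration nonlinearity,
spatially localized release events, cell-cycle or density effects, and
ATP degradation in the bath. Tests that pass on these ensembles therefore
validate the pipeline's statistical machinery (featurization, mixture
detection, dose-curve alignment) under controlled heterogeneity, not the
model's fidelity to any particular recording.

Bimodality of response magnitudes is called by comparing one- and
two-component Gaussian mixtures (equal- and free-variance families) and
declaring two modes when BIC improves by more than 10 — a conventional
"very strong evidence" margin, exposed as `delta_bic`.

## Problem sizes

The shipped tests and the reproduction script run at desk scale: 151-dose
sweeps at 120 s per dose for the dose-response geometry, a 60×60
slow-variable grid for the Hopf map, populations of 60–200 cells for the
mixture-recovery checks. These sizes were chosen so the full pipeline
(suite plus reproduction script) completes in a few minutes on one CPU
while keeping every detected extremum stable under grid refinement.

## Known limitations

* The IP~3~R submodel cannot produce slow decay after a rapid calcium
  rise; response shapes at the highest doses are dominated by the P2X7
  branch.
* Membrane potential is fixed (−60 mV); no P2X7 pore dilation; the naive
  and sensitized open states share one conductance.
* The sensitized-row binding rate caveat described above: the sensitized
  plateau level is the one headline quantity not reproduced under the
  tabulated `k7`.
* Basal IP₃ is assumed zero; the oscillatory-region crossing pattern is
  sensitive to that assumption.
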