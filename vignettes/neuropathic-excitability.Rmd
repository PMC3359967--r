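---
title: "Modeling the dynamical switch behind neuropathic sensory-neuron hyperexcitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the dynamical switch behind neuropathic sensory-neuron hyperexcitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgexcite)
```

## The scientific problem

After nerve injury, primary somatosensory (dorsal root ganglion, DRG)
neurons develop a triad of pathological behaviors: they switch from firing
a single spike at stimulus onset to firing repetitively during sustained
depolarization, they develop subthreshold membrane potential oscillations
(MPOs), and they burst. `drgexcite` implements a family of minimal
Morris-Lecar-type conductance models in which all three behaviors follow
from one underlying change: the dynamical mechanism of spike initiation
switching from a *quasi-separatrix crossing* (no bifurcation; the resting
state stays stable and only the route to it produces a spike) to a
*subcritical Hopf bifurcation* (the resting state itself destabilizes).
The package provides the models, a stochastic fixed-step integrator, and
the dynamical-systems toolbox (fixed points, eigenvalues, nullclines,
quasi-separatrix tracing, bifurcation diagrams with Hopf detection and
classification, fast-slow dissection of bursting) together with feature
extraction from simulated voltage traces.

## The models

The core 2-D model has a fast activation variable (membrane potential $V$,
with instantaneous activation $m$) and a slower recovery variable $w$:

$$C\frac{dV}{dt} = I_{stim} - g_{fast}\,m_\infty(V)\,(V-E_{Na})
  - g_{slow}\,w\,(V-E_K) - g_{leak}\,(V-E_{leak}) + n(t)$$
$$\frac{dw}{dt} = \phi_w\,\frac{w_\infty(V)-w}{\tau_w(V)},\qquad
  x_\infty(V) = \tfrac12\left[1+\tanh\!\frac{V-\beta_x}{\gamma_x}\right],\qquad
  \tau_w(V) = \frac{1}{\cosh\!\frac{V-\beta_w}{2\gamma_w}}$$

with $C = 2\,\mu F/cm^2$, $E_{Na} = 50$, $E_K = -100$, $E_{leak} = -70$ mV,
$g_{fast} = g_{slow} = 20$, $g_{leak} = 2\,mS/cm^2$, $\beta_m = -1.2$,
$\gamma_m = 18$, $\gamma_w = 10$ mV, $\phi_w = 0.15$. The half-activation
voltage of the slow current, $\beta_w$, is the pathology dial:
$\beta_w = -21$ mV is the "normal" phenotype, $-13$ mV the "neuropathic"
one, and $-19$ mV sits in the intermediate regime where the Hopf
bifurcation is *super*critical and a stable subthreshold limit cycle
(noise-independent MPOs) exists over a narrow current window.

Three-dimensional variants add one slow process each: cumulative sodium
channel inactivation `h` (fixed $\tau_h = 2000$ ms; the `"nainact-slow"`
preset, which also uses $\gamma_m = 15$ mV), AHP-current activation `z`
($g_{adapt} = 0.5\,mS/cm^2$, $\beta_z = 0$, $\gamma_z = 4$ mV,
$\tau_z = 300$ ms; the `"ahp"` preset, the elliptic burster), and the
"ungrouped" variant that splits the slow current into a delayed-rectifier
K$^+$ current and a separate subthreshold current whose reversal makes it
inward or outward. A fifth variant (`"s2-normal"`/`"s2-neuropathic"`)
replaces the potassium-activation feedback altogether with fast sodium
inactivation, to show that the normal-to-neuropathic switch does not
depend on which slow feedback implements it.

```{r}
ml_preset("neuropathic")
```

## Choices made where the source was ambiguous

Several constants are not printed in the text this package models; the
decisions below are the package's own and are fixed once:

* **Sign of $\beta_h$ in the slow-inactivation model.** The parameter list
  for the slow-inactivation variant is printed as "$\beta_h$ = 30 mV"
  with $\gamma_h = -5$ mV. At $+30$ mV, $h_\infty$ only falls below 0.99
  above $+18$ mV, spikes barely graze the inactivation zone, cumulative
  inactivation never exceeds ~1%, spike trains never terminate, and the
  40% inactivation level ($h = 0.6$) analyzed with the clamped-`h`
  diagrams is unreachable from any subthreshold potential. With
  $\beta_h = -30$ mV the rest state still has $h \approx 1$,
  $h_\infty(-31\,mV) \approx 0.6$ -- exactly 40% inactivation at the
  depolarized potentials where MPOs occur -- and depolarization produces
  progressive inactivation, a rising spike threshold and train
  termination. The preset therefore uses $\beta_h = -30$ mV, reading the
  printed value as having lost its sign.
* **Noise discretization.** "Gaussian white noise with 0 mean and
  20 mV$^2$ variance" in a fixed-step Euler scheme is ambiguous about
  per-step scaling. The package uses a dt-invariant Wiener convention
  referenced to a 0.05-ms step: the per-step voltage kick has standard
  deviation $\sqrt{\sigma^2 \cdot 0.05 \cdot dt}$ (mV), which coincides
  with drawing $N(0, \sigma^2)$ directly per Euler step at
  $dt = 0.05$ ms, the upper end of the integration steps the original
  analyses used. Referencing the same draw to a 1-ms step instead (a
  20-fold larger noise intensity) makes 20 mV$^2$ noise overwhelm the
  dynamics: the model then spikes incessantly within ~10 mV of threshold,
  no confined MPO band exists, and bursting is destroyed -- inconsistent
  with the phenomena the noise is meant to perturb, which is why that
  reading was rejected. The convention is switchable
  (`noise_scaling`, `noise_ref_dt` in `simulate_model()`).
* **Rate scale $\phi_h$ of the fast-inactivation variant.** Unstated in
  the source. Small values (including $\phi_w$'s 0.15) make the
  $\beta_h = -30$ "normal" configuration itself bifurcate and fire
  repetitively at ~45 $\mu A/cm^2$, destroying the intended contrast.
  $\phi_h = 0.8$ keeps inactivation slow enough relative to the upstroke
  to permit sustained spiking at $\beta_h = -27$ yet fast enough that the
  $-30$ configuration never destabilizes (onset-only spiking at every
  current tested up to 200 $\mu A/cm^2$). Note a transcription limit: in
  this variant repetitive spiking at $\beta_h = -27$ begins where the
  resting branch vanishes at a *fold* of the N-shaped steady-state I-V
  curve rather than at a traced subcritical Hopf; no $\phi_h$ exists
  under the standard gating forms that produces a resting-branch Hopf at
  $-27$ while keeping $-30$ onset-only.
* **Ungrouped-current calibration.** The subthreshold current's
  $(g_{sub}, \beta_y, \gamma_y)$ are fitted by least squares
  (`calibrate_isub()`) so the steady-state $(I_{K,dr}+I_{sub})$-V curve
  reproduces the $\beta_w\!: -21 \to -13$ shift of the 2-D model's
  $I_{slow}$-V curve over $V \in [-70, -20]$ mV; the fitted values ship
  as preset defaults and the behavioral match is verified in the tests
  (the inward-calibrated model fires repetitively at 45 $\mu A/cm^2$ like
  the neuropathic 2-D model; the outward-calibrated one is onset-only at
  60 like the normal model, with Hopf currents of 39.3 vs 42.8 and 86.2
  vs 87.3 $\mu A/cm^2$ respectively).

## Integration and its conventions

`simulate_model()` integrates with forward Euler (Euler-Maruyama under
noise) at $dt \in [0.005, 0.05]$ ms, default 0.01 ms. Euler is first
order: spike *times* drift cumulatively at finer tolerances even while
spike counts, thresholds and bifurcation structure are converged, so the
dt-convergence test pins early-spike times (< 0.5 ms shift when halving
dt) and the spike count, not whole-train phase. Gates are clamped to
$[0,1]$ after each step (only reachable under extreme noise or
far-from-physiological states; `strict_gates = TRUE` raises instead).
`"settled"` initial conditions settle the noiseless model at the baseline
current and error informatively when no stable fixed point exists there.
Weak noise around the curved I-V relation biases the mean trace by
~0.3 mV relative to the noiseless trajectory; the ensemble test allows
for that rectification offset.

## Dynamical analysis

Fixed points reduce to a scalar root-find in $V$ (all gates at steady
state) on a $[-90, 40]$ mV bracket with 27 multi-start intervals;
eigenvalues come from analytic Jacobians for the 2-D variants and central
finite differences ($10^{-6}$) for the 3-D ones. Hopf points are located
by bisection on the real part of the tracked complex pair (parameter
resolved far below $10^{-3}$; $|\mathrm{Re}\,\lambda| < 10^{-6}$ at the
reported point).

Limit-cycle branches are tracked by slow bidirectional parameter
continuation of forward simulations rather than collocation continuation,
so unstable cycles are not traced; subcriticality is inferred from
bistability instead of a Lyapunov coefficient. One subtlety the
classification must respect: a large spiking cycle can coexist with the
stable fixed point below a *super*critical Hopf as well (the large
cycle's fold can lie below the Hopf -- it does at $\beta_w = -19$), so
`classify_hopf()` first tests whether the cycle amplitude grows
continuously from zero when the trajectory departs from the destabilized
fixed point (squared amplitude locally linear in the parameter), and only
then accepts large-amplitude bistability as subcritical evidence.
Ambiguous evidence returns `"indeterminate"` with diagnostics.

The quasi-separatrix is seeded automatically: bisect spiking against
non-spiking initial conditions along a transect through the stable fixed
point, follow the two near-boundary trajectories forward until they
diverge after clinging to the QS, and integrate backward in time from the
divergence locus -- the backward flow contracts onto the QS and slides
along it. Near-boundary responses of the onset-only model are graded, not
all-or-none, so the divergence criterion adapts to half the maximal
trajectory separation. The first few millimeters of curve nearest the
seed are still converging onto the manifold and should not be
over-interpreted.

Fast-slow dissection of the burster freezes `z`, builds the z-swept
diagram of the fast subsystem, and overlays the z-nullcline and
$V_{equivalent}$ -- the constant voltage whose adaptation drive equals
the cycle-averaged $z_\infty(V(t))$ on the spiking branch, obtained
through the analytic Boltzmann inverse. Bursting is predicted when the
slow flow on the spiking branch is still positive where the stable cycle
ends (the would-be equilibrium is unreachable), tonic firing when the
flow has a stable zero inside the branch, quiescence when the z-nullcline
intersects the stable fixed-point branch. During full-model bursting the
slow passage effect carries `z` slightly past both static boundaries
(~0.002-0.005 here), which the agreement tests allow for.

## Feature extraction

Spikes are upward crossings of 0 mV with a 2-ms refractory floor; the
response to a step is `onset_only` when all spikes fall within 100 ms of
onset and `repetitive` when spiking reaches the final third of the step;
trains that die in the middle are reported `"other"`, not forced.
Thresholds are bisected to 0.01 $\mu A/cm^2$; the repetitive threshold is
independently cross-checked against the Hopf current (they agree within
1 $\mu A/cm^2$ for the 2-D presets -- the simulated threshold sits at the
fold of the large cycle, slightly below the Hopf, which is the bistable
window itself). MPO spectra are Welch averages (1024-ms Hann segments,
50% overlap, one-sided density normalized to recover variance) over
spike-free stretches; a peak is "discernible" when the density, smoothed
over ~7 Hz, reaches twice the 5-100 Hz median. The smoothing matters:
genuine MPO peaks are broad (quality factor < 5), while the chi-squared
scatter of raw Welch bins hovers at the 2x knife edge far below
threshold -- the low-frequency relaxational shoulder then wins the
"peak" and the call flips from seed to seed. With smoothing, 10-s traces
and a 5-seed majority vote, the negligible-vs-present dichotomy is
stable across seeds.
Burst grouping splits the ISI distribution in two (2-means on log ISIs,
refined toward a quarter of the median interburst gap, with guards for
noise-shortened quiescent phases); unimodal trains are flagged tonic.
The dV/dt-inflection spike threshold searches the curvature maximum on
the upstroke *foot* (final approach below 5 mV/ms); it reads the
regenerative take-off voltage, which sits a few mV depolarized to the
Hopf-point voltage (about +3 mV in the $\gamma_m = 15$ family, +7 mV in
the standard neuropathic model).

## What the simulations do and do not show

Everything here is synthetic: single-compartment dynamics, additive
Gaussian voltage noise, no channel-number stochasticity, no morphology,
no temperature dependence, and no fitting to experimental voltage traces.
Passing tests demonstrate that the *dynamical* account -- QS-crossing
versus subcritical Hopf, noise-dependent MPOs confined near threshold,
elliptic bursting from adaptation dragging the fast subsystem across a
bistable window, and the degeneracy of parameter changes producing the
same switch -- is internally consistent and quantitatively reproducible.
They say nothing about whether a given real DRG neuron implements these
parameters; the model family's point is precisely that many molecular
configurations map onto the same two dynamical phenotypes.

Problem sizes were chosen to keep every analysis deterministic-feeling
and fast: bifurcation sweeps use 17-61 grid points with per-point
transients of 300-800 ms, MPO measurements use 8-10 s traces with 2-5
seeds, and the full figure-scenario registry (`run_scenario()`) completes
in well under 15 minutes at default resolutions on one core.

## Worked example

```{r, eval = FALSE}
p <- ml_preset("neuropathic")
hopf_point(p, c(0, 100))[c("I_hopf", "V_hopf")]
#> $I_hopf  42.80154
#> $V_hopf  -38.53519

tr <- simulate_model(p, stim_protocol(amp = 45, offset = 1000),
                     duration = 1000, thin = 10L)
classify_response(detect_spikes(tr), stim_protocol(amp = 45, offset = 1000),
                  1000)
#> [1] "repetitive"
```

Parameter sets serialize to JSON and YAML (`write_params()` /
`read_params()`); trajectories and diagram branches write to CSV with
JSON sidecars. A thin command-line front end over these functions ships
in `inst/cli/neuroexcite.R`.
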