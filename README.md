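# drgexcite

Minimal conductance-based models and dynamical-systems analysis of
neuropathic hyperexcitability in dorsal root ganglion (DRG) sensory
neurons.

After nerve injury, DRG somata switch from firing one spike at stimulus
onset to firing repetitively, develop subthreshold membrane potential
oscillations (MPOs), and burst. This package implements a family of
Morris-Lecar-type models in which that whole triad follows from a single
dynamical change: spike initiation switching from a quasi-separatrix
(QS) crossing to a subcritical Hopf bifurcation. For R users in
computational neuroscience it provides the model family, a compiled
Euler/Euler-Maruyama integrator with additive membrane noise, and the
analysis toolbox used to make that argument quantitative.

## The model

The 2-D core is

    C dV/dt = I_stim - g_fast m_inf(V) (V - E_Na) - g_slow w (V - E_K)
              - g_leak (V - E_leak) + n(t)
    dw/dt   = phi_w [w_inf(V) - w] / tau_w(V)

with Boltzmann steady states `x_inf(V) = 0.5 [1 + tanh((V - beta_x) / gamma_x)]`
and `tau_w(V) = 1 / cosh((V - beta_w) / (2 gamma_w))`. The slow current's
half-activation voltage beta_w is the pathology dial: -21 mV (normal,
onset-only spiking through a QS crossing), -13 mV (neuropathic,
repetitive spiking through a subcritical Hopf), -19 mV (supercritical
Hopf with noise-independent subthreshold oscillations). Three-dimensional
variants add slow sodium inactivation, AHP-mediated adaptation (the
elliptic burster), or split the slow current into delayed-rectifier and
subthreshold components; a further 2-D variant replaces potassium
activation with sodium inactivation as the slow negative feedback. All
variants are available as named presets (`ml_preset()`).

## Worked example

```r
library(drgexcite)

p <- ml_preset("neuropathic")
hopf_point(p, c(0, 100))[c("I_hopf", "V_hopf")]
#> $I_hopf
#> [1] 42.80154
#> $V_hopf
#> [1] -38.53519
```

The neuropathic model destabilizes through a subcritical Hopf at
42.8 uA/cm2 (fixed point at -38.5 mV): below that current it rests
quietly, above it it fires repetitively, and the just-suprathreshold
stimulus of 45 uA/cm2 elicits sustained spiking:

```r
prot <- stim_protocol(amp = 45, onset = 0, offset = 1000)
tr <- simulate_model(p, prot, duration = 1000, thin = 10L)
classify_response(detect_spikes(tr), prot, 1000)
#> [1] "repetitive"

# the normal model fires exactly once at 60 uA/cm2 (QS crossing, no Hopf)
pn <- ml_preset("normal")
protn <- stim_protocol(amp = 60, onset = 0, offset = 1000)
length(detect_spikes(simulate_model(pn, protn, duration = 1000,
                                    thin = 10L))$times)
#> [1] 1
```

Bifurcation diagrams, phase planes and the burst analysis follow the same
pattern:

```r
dg <- bifurcation_diagram(p, range = c(38, 48), n = 41)
dg
#> <bifurcation_diagram> sweep of I_stim over [38, 48] (41 points)
#>   hopf at I_stim = 42.8015
#>   fold_of_limit_cycles at I_stim = 42.875
#>   fold_of_limit_cycles at I_stim = 42.125
ev <- Filter(function(e) e$type == "hopf", dg$events)[[1]]
as.character(classify_hopf(dg, ev))
#> [1] "hopf_subcritical"

fs <- fast_slow_analysis(ml_preset("ahp"), I_stim = 43)
fs
#> <fast_slow_result> I_stim = 43: predicted regime 'bursting'
#>   fast-subsystem Hopf (burst onset) z = 0.0061; stable cycle ends (burst offset) z = 0.0250
```

The two fold-of-limit-cycles flags bracket the bistable window around the
subcritical Hopf: the large spiking cycle is born at 42.1 uA/cm2 on the
down-sweep and the up-sweep jumps onto it just above the Hopf, which is
the hysteresis elliptic bursting exploits.

Each figure-level analysis is packaged as a scenario with a qualitative
self-check (`run_scenario("fig2")`, ..., `run_scenario("figS4")`); a thin
command-line wrapper lives in `inst/cli/neuroexcite.R`.

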