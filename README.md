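# mfcircuit

Simulation and input–output analysis of a reduced cortical circuit
model: two recurrent excitatory ensembles coupled through effective
global inhibition. The package is built for computational
neuroscientists who want to map how the balance of self-excitation and
cross-inhibition shapes a local circuit's response to sensory-like
transient inputs and to slow oscillatory background activity — the
modelling framework used to interpret top-down (e.g. motor-to-sensory)
cortical feedback as a change in effective synaptic weights.

## The model

Each ensemble is a mean-field unit whose activity is a synaptic gating
variable *S* ∈ [0, 1]. The firing rate follows the transfer function

    r = f(I) = (a·I − b) / (1 − exp(−d·(a·I − b)))

with a = 270 Hz/nA, b = 108 Hz, d = 0.154 s. The total input currents
couple the two ensembles symmetrically,

    I₁ = Js·γ·S₁ − Jo·γ·S₂ + Istim₁ + Inoise₁
    I₂ = Js·γ·S₂ − Jo·γ·S₁ + Istim₂ + Inoise₂

where Js ≥ 0 is the net self-excitation, Jo ≥ 0 the net cross-inhibition
magnitude, and the couplings weight the saturating synaptic drive γ·S
(see the methods vignette for why this convention, rather than weighting
*S* directly, yields the documented transient/sustained regime
structure). Gating integrates the rate with saturation,

    dS/dt = −S/τs + (1 − S)·γ·r ,   γ = 0.641, τs = 100 ms,

and each ensemble receives an independent Ornstein–Uhlenbeck background
current with mean Io, correlation time 10 ms, and stationary SD
σ_noise. Stimuli are 10 ms current pulses low-pass filtered with a
10 ms time constant, plus an optional common 2 Hz sinusoid emulating a
propagating slow oscillation.

On top of the integrator the package provides the study protocols
(coincident-stimulus series, proportional transient series, sinusoidal
drive), (Js, Jo) parameter sweeps, the input–output metric set
(trial-to-trial reliability, stimulus–response cross-correlation
amplitude and decay, time to half-maximal cumulative response, band
power), and a synthetic LFP/MUA session generator with controllable
ground truth for testing the analysis pipeline offline.

## Worked example

Classify the three exemplar operating regimes under the 13-stimulus
coincident protocol (ensemble 1 fixed at 0.5 nA, ensemble 2 scaled from
0 to 4× that; Io = 0.32 nA, σ_noise = 0.001 nA):

```r
library(mfcircuit)
for (p in list(c(0.17, 0.01), c(0.33, 0.33), c(0.65, 0.33))) {
  res <- run_coincident_protocol(p[1], p[2], seed = 1)
  cat(sprintf("Js=%.2f Jo=%.2f  %-9s  dS1=%.3f  crossing=%d\n",
              p[1], p[2], res$regime, res$delta_s1, res$crossing))
}
```

```
Js=0.17 Jo=0.01  transient  dS1=0.009  crossing=4
Js=0.33 Jo=0.33  transient  dS1=0.279  crossing=4
Js=0.65 Jo=0.33  sustained  dS1=0.782  crossing=11
```

`dS1` is the cross-suppression index: the drop in ensemble 1's peak
response between the first stimulus (no competing input) and the last
(competitor at 4× its own input). Low couplings leave the ensembles
nearly independent (dS1 ≈ 0); mid couplings give graded suppression
with the two peak trajectories crossing exactly at the matched-input
stimulus (index 4); high couplings produce winner-take-all persistence,
a near-total collapse of the suppressed ensemble (dS1 > 0.5), and a
right-shifted crossing — ensemble 2 must substantially out-drive
ensemble 1 before it takes over.

The full campaigns live in `analysis/01_circuit_regimes.R` through
`analysis/05_synthetic_sessions.R`; each writes its metric tables and a
JSON run manifest under `results/`.

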