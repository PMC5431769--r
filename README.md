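# rtfsim

Stochastic mechanochemical simulation of regulated thin filament
activation — from a single myosin molecule to a half-sarcomere.

## The problem

In striated muscle, contraction is switched on by calcium acting through
troponin (Tn) and tropomyosin (Tm) on the actin thin filament, but myosin
itself also activates the filament: a strongly bound head displaces Tm and
raises the attachment rate of its neighbours. Because both mechanisms
operate at once, their relative contributions are hard to separate in any
single experiment. `rtfsim` implements a two-parameter regulation model
that de-convolves them, together with Monte-Carlo simulators for the three
assay geometries in which the model is constrained — the three-bead
laser-trap assay (single molecule and ~14-head mini-ensemble), the in vitro
motility assay (~75 heads), and an isometric half-sarcomere (~300 heads) —
plus the trace-analysis event detectors and curve-fitting routines used to
reduce such data.

## The model

Calcium sets the single-molecule weak-to-strong attachment rate relative to
the unregulated rate:

    epsilon = eps_min^(1 - theta) * eps_max^theta,
    theta   = [Ca] / (K + [Ca])

with `eps_min = 0.006` (no calcium), `eps_max = 0.5` (saturating calcium)
and `K` the Michaelis constant of TnC for calcium (~0.2 uM). Myosin-based
activation is a coupling distance `l = 400 nm`: two strongly bound heads
closer than `l` fully activate the intervening filament; a single bound
head partially activates it (multiplier `epsilon^1/2`). Each head cycles
through a lumped four-state scheme — attachment at
`(geometry base rate) x (activation multiplier)`, load-dependent ADP
release `k_D0 * exp(-F * delta / kBT)`, and ATP-induced rigor detachment
`k_T * [ATP]` with `k_T = 3 uM^-1 s^-1` — with linear-elastic motor links
(`k_m = 0.3 pN/nm`, powerstroke `d = 10 nm`). In the trap the base
attachment rate follows the ladder 2.2 / 36 / 40 s^-1 for the first,
second, and later heads.

## Worked example

```r
library(rtfsim)

## calcium dependence of the single-molecule attachment rate
reg <- regulation_params(K_uM = 0.216)
round(epsilon_ca(pca_to_conc(c(4, 5, 6, 7, 9)), reg), 4)
#> [1] 0.4953 0.4554 0.2279 0.0243 0.0061

## Hill fit of that curve (concentration scale, with baseline)
fit_hill(c(4, 5, 6, 7, 9), epsilon_ca(pca_to_conc(c(4, 5, 6, 7, 9)), reg))
#> Hill fit: pCa50 = 5.931 +/- 0.027, alpha = 1.177 +/- 0.107
#>   amplitude = 0.4925, baseline = 0.002733, weighted RSS = 4.943e-05

## a mini-ensemble trap record at pCa 5, scored with the 8 nm / 10 ms
## threshold detector
cfg <- trap_config(k_trap = 0.038, n_motors = 14, atp_uM = 100,
                   pca = 5, seed = 1)
tr <- simulate_trace(cfg, regulation_params(K_uM = 0.2))
str(event_stats(detect_threshold(tr), 10))
#> List of 6
#>  $ frequency_hz        : num 5
#>  $ n_events            : int 50
#>  $ mean_duration_ms    : num 31.6
#>  $ median_duration_ms  : num 23.6
#>  $ mean_peak_force_pN  : num 1.83
#>  $ mean_displacement_nm: num 24.6

## recover K from a noisy synthetic activation curve
g <- make_activation_curve(reg = reg, seed = 2)
fit_K(g$curve, reg)
#> K fit: K = 0.1733 uM (chi2 = 0.508 on 4 dof, p = 0.973)
```

The relative-rate curve spans the ~50-fold increase from calcium-free to
saturating calcium; its shallow Hill coefficient (~1.2-1.4) is the
single-molecule benchmark against which the steeper, left-shifted
half-sarcomere force-pCa curve (simulated with `simulate_fiber_force()`)
demonstrates myosin-binding cooperativity. `event_stats()` mirrors the
experimental bookkeeping: events per second of record, mean lifetime,
peak trap force.

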