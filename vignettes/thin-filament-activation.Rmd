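---
title: "Modelling calcium- and myosin-dependent thin filament activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium- and myosin-dependent thin filament activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtfsim)
```

## The regulation model

`rtfsim` treats thin-filament activation as the product of two separable
mechanisms.

**Calcium acts on the single molecule.** The weak-to-strong transition of
one myosin head on a regulated filament, relative to the same transition on
bare actin, is

$$\varepsilon([\mathrm{Ca}]) = \varepsilon_{min}^{\,1-\theta}\,
  \varepsilon_{max}^{\,\theta}, \qquad
  \theta = \frac{[\mathrm{Ca}]}{K + [\mathrm{Ca}]},$$

where $\theta$ is the Michaelis–Menten saturation of troponin C with
calcium. The geometric interpolation is equivalent to a free-energy barrier
for strong binding that falls linearly with $\theta$: regulation imposes an
activation barrier whose height, not its attempt frequency, is
calcium-dependent. $\varepsilon$ runs from $\varepsilon_{min} = 0.006$
(calcium-free) to $\varepsilon_{max} = 0.5$ (saturated; the regulatory
proteins halve attachment even at high calcium). The single fitted
parameter is $K$ (~0.2 µM).

**Myosin binding acts locally over a coupling distance.** A strongly bound
head displaces tropomyosin over a span $\ell = 400$ nm to either side.
Motors flanked within $\ell$ on *both* sides see a fully activated filament
(attachment multiplier 1); motors with a bound neighbour on exactly one
side see partial activation. The partial-activation multiplier is
$\varepsilon^{p}$ with $p = 0.5$ by default — the geometric mean of the
inactive ($\varepsilon$) and active (1) limits, i.e. half of the
regulatory barrier removed. The exact single-sided rule is a genuinely
open modelling choice; $p$ is exposed as `partial_exponent` so alternative
rules can be substituted, and $p = 0.5$ is the package's default because it
is the unique choice consistent with the barrier picture above when one of
the two flanking constraints is released. Distances are measured
anchor-to-anchor along the filament axis, and "within $\ell$" is a strict
inequality. Setting `ell_nm = 0` switches cooperativity off entirely;
setting `eps_min = eps_max` switches calcium regulation off.

## The crossbridge cycle

Each head follows a lumped four-state scheme: DETACHED → (weak, lumped) →
STRONG_ADP → RIGOR → DETACHED. The effective attachment rate is a
geometry-supplied base rate times the activation multiplier; ADP release is
load-dependent (Bell), $k_{D} = k_{D0} e^{-F\delta/k_BT}$ (clamped at
$e^{5} k_{D0}$ for strongly assisting loads); rigor detachment is
$k_T[\mathrm{ATP}]$ with $k_T = 3\ \mu M^{-1} s^{-1}$. Motor links are
linear springs.

Parameter defaults, with the reasoning behind the ones the package had to
choose itself:

| parameter | default | unit | why |
|---|---|---|---|
| `k_ws` | 40 | s⁻¹ | solution weak-to-strong rate |
| `k_a_single` | 2.2 | s⁻¹ | trap geometry-limited first attachment |
| `k_a2` | 36 | s⁻¹ | second head, fluctuations partly damped |
| `k_T` | 3 | µM⁻¹s⁻¹ | ATP-induced rigor detachment |
| `d_stroke` | 10 | nm | powerstroke; trap event amplitude ≈ `k_m d/(k_m+k_trap)` ≈ 9 nm |
| `k_m` | 0.3 | pN/nm | motor stiffness |
| `k_D0` | 500 | s⁻¹ | unloaded ADP release; sets the detachment-limited unloaded gliding speed `d·k_D0` ≈ 5 µm/s, typical of fast skeletal myosin at 30 °C |
| `delta_nm` | 1.0 | nm | Bell distance for ADP release |
| `kBT` | 4.14 | pN·nm | 30 °C |

`k_D0` and `delta_nm` are not constrained by the assays' printed summary
numbers alone; they were fixed once from the gliding-speed argument above
and are config-exposed, never hard-coded.

## Simulation geometries

**Laser trap (`simulate_trace`).** The bead–actin–bead dumbbell is one
effective coordinate $x$ with combined trap stiffness `k_trap` and drag
`gamma` (default 7.5×10⁻⁶ pN·s/nm, the Stokes drag of a 1-µm bead at
30 °C). Between kinetic transitions $x$ is an Ornstein–Uhlenbeck process
(trap spring + attached motor springs, thermal noise at equipartition),
discretised *exactly* — the update
$x \leftarrow \mu + (x-\mu)e^{-k\Delta t/\gamma} +
\sqrt{(k_BT/k)(1-e^{-2k\Delta t/\gamma})}\,\xi$ is unbiased at any step
size, so baseline variance matches $k_BT/k_{trap}$ to Monte-Carlo error.
Kinetic transitions fire per step with probability rate·Δt; the integrator
refuses configurations with rate·Δt ≥ 0.2. Defaults: Δt = 25 µs,
4 kHz output sampling (exactly 10 steps per sample). Motors attach at
their anchors (the 2.2/36/40 ladder already folds binding-site
availability into the rates); anchors are spaced 36 nm — approximately one
actin pseudo-repeat, and consistent with the ~0.5 µm chord of a 3-µm
pedestal bead that lies within myosin reach of the filament, so that 14
heads span ~470 nm. Every trace carries its configuration and the
ground-truth binding intervals as attributes.

**Motility (`simulate_motility`).** 75 heads spaced evenly under a 1-µm
rigid filament (13.3 nm spacing). The unloaded filament sits
quasi-statically at the zero-net-force position of the attached springs
(filament drag is negligible against motor spring forces), so all rates
are piecewise constant and the kinetics are simulated exactly by the
Gillespie algorithm. Attachment uses `k_ws` (no trap height limitation on
a surface). Speed is measured after discarding the first 10% of the run:
tracked filaments in the real assay are already translocating, and the
start-up from the all-detached initial state would otherwise bias low-
calcium speeds. The published filters are applied to curve summaries:
filaments shorter than 0.5 µm are eliminated and replicates slower than
0.13 µm/s are counted as stationary; stationary replicates are excluded
from mean speeds by default (the filter language parallels the length
elimination) but `include_stationary = TRUE` restores them.

**Half-sarcomere (`simulate_fiber_force`).** 300 heads at the motility
spacing, filament held fixed (isometric); the reported force is the
time-averaged total spring force of bound heads after a 10% transient,
normalised to the saturating-calcium value for Hill fitting.

## Event detection and its calibration

Three detectors mirror the experimental analysis chain, all returning the
same event table (start, duration, mean displacement, peak trap force):

* `detect_threshold()` — boxcar-smoothed, median-baseline-corrected
  excursions > 8 nm lasting ≥ 10 ms;
* `detect_variance_drop()` — sliding-window variance ≤ 50% of the record's
  median windowed variance, in runs ≥ 10 ms;
* `detect_page()` — a two-sided Page cumulative-sum test on the windowed
  log-variance; attachment is dated to the start of the alarm excursion
  and detachment by a second cusum referenced to the event's own variance
  level.

The published criteria fix the 8 nm / 10 ms / 50% thresholds but not the
bandwidth or decision levels. Those were calibrated on *synthetic
motor-free baselines* (the experiment's negative control) at both printed
trap stiffnesses, choosing for each free constant the least aggressive
value that produced zero false events in 540 s of baseline: smoothing
10 ms, variance window 20 ms, Page window 5 ms with threshold 30 and
drift 0.5. Two consequences are worth knowing. First, a genuine binding
event reduces the position variance about nine-fold
($k_{trap}/(k_{trap}+k_m) \approx 0.11$), far below the 50% criterion, so
calibration costs little sensitivity there. Second, a *two-fold* variance
drop lasting only 50 ms carries roughly 2.4 nats of evidence — below any
zero-false-alarm decision level — so the Page detector is validated in the
test suite on four-fold drops, where its recall is 1.0 and onset timing is
within 5 ms. Detection losses are part of the model's output by design:
simulated records are always scored by the same detectors as data, so
short events (the majority at 100 µM ATP, where attachments last ~5 ms)
are undercounted in the simulation exactly as they are in the experiment.

At 1 µM ATP single-molecule events last ~0.3 s and occupy a large fraction
of the record, so raw events-per-second saturates below the attachment
rate. `single_molecule_frequency()` therefore also reports the
occupancy-corrected attachment rate (events per second of *detached* time),
which is the quantity that recovers $\varepsilon$ when divided by the
unregulated 2.2 s⁻¹.

## Fitting

* `fit_hill()` fits $y = base + amp\,C^{\alpha}/(C_{50}^{\alpha} +
  C^{\alpha})$ in *concentration* (not pCa), weighted by 1/sd² when
  uncertainties are supplied, with multi-start over $\alpha \in
  \{0.5, 1, 2, 4\}$. The baseline term is included because single-molecule
  binding does not vanish at zero calcium ($\varepsilon_{min} > 0$).
* `fit_K()` is a one-dimensional weighted least-squares over $K$ with
  $\varepsilon_{min}, \varepsilon_{max}$ fixed a priori; goodness of fit is
  $\chi^2 = \sum((obs-pred)/sd)^2$ on $n-1$ degrees of freedom with an
  upper-tail p-value. Zero or missing uncertainties trigger an unweighted
  fallback with a warning.
* `bootstrap_K()` resamples individual recordings within each calcium
  level — the finest experimental unit — and summarises replicate fits by
  median and quartiles; fully seeded.
* `fit_epsilon_per_condition()` estimates a calcium-independent
  $\varepsilon$ from speed-vs-ATP data by simulation matching (log grid +
  parabolic refinement); when every ATP point lies below the critical
  concentration the objective is flat in $\varepsilon$ and the fit is
  flagged unidentifiable rather than returning a spurious value.
* `ell_sensitivity()` refits $K$ and scores trap + motility predictions
  for each candidate coupling distance, reporting the χ² profile and the
  95% band around its minimum.

## The synthetic-data generators

`make_trace()` produces baseline noise as an Ornstein–Uhlenbeck process at
equipartition variance $k_BT/k_{trap}$ with corner rate $k_{trap}/\gamma$
(a trapped bead has a Lorentzian, not white, spectrum); scheduled events
offset the mean and rescale the variance, and the schedule is returned as
ground-truth labels. `make_activation_curve()` evaluates the regulation
model and emulates replicate recordings with multiplicative noise —
record-level CV 0.39 (matching the scatter of the printed saturating-
calcium frequency, 0.85 ± 0.33 s⁻¹) and 3 records per calcium level
("several" ~10-s recordings). The curve's per-point `sd` is the
generator's known noise level, as a figure's error bars would be, not the
3-sample estimate.

What the generators deliberately do not emulate: instrument filtering and
camera/QPD artefacts, bead rotation, filament compliance within the
dumbbell, surface dead-heads, and field-of-view-level variability in the
motility assay. Passing tests therefore certify the analysis chain against
the model's own statistics at realistic SNR, not against every systematic
present in real records.

## Problem sizes

The test suite and the reproduction script run at desk scale, chosen so
the full suite completes in well under a minute of simulation per module:
30 × 10-s mini-ensemble traces at pCa 5 and 300 at pCa 9; motility curves
with 9 replicates per (pCa, ATP) condition over a 9-point ATP grid;
half-sarcomere runs of 5 s × 3 replicates over 12 calcium levels; 500
synthetic activation curves for the parameter-recovery study; 300-replicate
null-calibration of the χ² p-value.

## Known limitations

* **Rigid isometric coupling overstates fiber cooperativity.** With the
  filament clamped rigidly, every bound head is pinned at full powerstroke
  strain (3 pN), which halves its ADP release rate and roughly doubles its
  attached lifetime. That strengthens strong-binding activation: the
  simulated half-sarcomere force–pCa curve is steeper *and further
  left-shifted* (pCa₅₀ ≈ 7.2 in the test-suite run) than a compliant
  half-sarcomere would produce. The qualitative prediction — fiber curve
  steeper and left-shifted relative to the single-molecule curve — is
  robust; the absolute pCa₅₀ is sensitive to the rigid-clamp idealisation.
* **Residual creep at low calcium.** Above the critical ATP at pCa 9,
  sporadic uncooperative attachments still advance the filament at
  ~0.2 µm/s, slightly above the 0.13 µm/s stationary cutoff; the model
  reproduces the speed collapse but not complete arrest.
* **Mini-ensemble event frequency at high calcium runs ~30% above the
  measured 4.1 s⁻¹** under the stated conditions; ground-truth counting
  shows the detector is faithful (the model itself generates ~5.5
  qualifying events/s), so the gap lies in the model conditions, not the
  analysis.
* The dumbbell is a single coordinate: no differential bead motion, trap
  anharmonicity, or axial (z) fluctuations beyond what the attachment-rate
  ladder already encodes.
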