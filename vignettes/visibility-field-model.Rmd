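---
title: "A stochastic neural field model of low-contrast visibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic neural field model of low-contrast visibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visfield)
```

## The problem

A thin, low-contrast line segment sits near the visibility threshold: small
contrast changes, random fluctuations in detector activation, relocations of
the object, and interruptions of stimulation all threaten to flip it between
visible and invisible. Psychophysically, visibility of such objects turns out
to be remarkably stable — initially bistable (sometimes seen, sometimes not),
but once established, maintained across many unpredictable relocations with a
per-presentation switch probability of only a few percent, and
history-dependent (hysteresis under gradually rising versus falling
contrast). This package implements a dynamic neural field model of those
phenomena, together with generators for the ten psychophysical protocols that
probe them and the analysis procedures that summarize them.

## The model

The core is a classic two-layer Amari-type activation dynamics over a
one-dimensional retinal coordinate $x$, augmented by a memory trace, input
adaptation, and a slow stochastic resting-level offset:

$$
\tau_u \dot u(x) = -u + h_u + n(t) + g_m (K_{\sigma_m} * m)(x)
  + S_{\mathrm{eff}}(x) + (w_{uu} * f(u))(x) - (w_{uv} * f(v))(x)
$$
$$
\tau_v \dot v(x) = -v + h_v + (w_{vu} * f(u))(x)
$$

with the sigmoidal rate function $f(z) = 1/(1 + e^{-\beta z})$ and the
visibility threshold at $z = 0$: localized activation with $u > 0$ means the
stimulus at that location is detected. All couplings $w$ are
integral-normalized Gaussians. Stimulus input is a Gaussian bump whose peak
amplitude is the "stimulus-initiated activation" mapped from Michelson
contrast (see below).

Four slower processes shape the history dependence:

* **Memory trace** $m(x)$: builds toward $f(u)$ with time constant
  `trace_build_tau` wherever activation is above threshold, and decays with
  the much longer `trace_decay_tau` elsewhere. Its effect on $u$ is a
  saturating resting-level boost
  $g_m \min\{(K_{\sigma_m} * m)(x),\, m_{\mathrm{sat}}\}$, where
  $K_{\sigma_m}$ is a unit-integral Gaussian of width `trace_spread`. The
  spread is wide — comparable to the ±12.8-arcmin relocation window — so the
  preactivation left by a visible object covers the whole region where the
  object can reappear; this is the mechanism that lets visibility "bridge"
  blank intervals and carry over to an unpredictable new location. The
  saturation (`trace_sat`) sits at a level that a single visible
  presentation already reaches: a longer history of presentations does not
  keep stabilizing without bound. That ceiling is what lets adaptation
  dominate when the starting contrast is repeated (repetitions add
  adaptation but almost no extra preactivation) while a single presentation
  still facilitates a later probe at full strength. The trace itself builds
  strictly locally (only where $u > 0$), so subthreshold stimulation leaves
  no trace.
* **Adaptation** $a(x) \in [0, 1]$: builds toward 1 with `adapt_tau` where
  activation is above threshold, decays with `adapt_decay_tau` elsewhere.
  It weakens stimulus input multiplicatively,
  $S_{\mathrm{eff}} = S \cdot (1 - g_a (K_{\sigma_a} * a))$ clipped at zero,
  so adaptation only matters where there has recently been above-threshold
  activation — an invisible (subthreshold) stimulus does not adapt.
* **Slow resting-level noise** $n(t)$: a single spatially uniform
  Ornstein-Uhlenbeck process with stationary SD `noise_slow_amp` and time
  constant `noise_slow_tau` of several seconds, standing in for slow drift of
  the observer's sensitivity. It is the main source of trial-to-trial
  bistability: detection of a near-threshold input succeeds when the offset
  happens to be high and fails when it is low, while its slowness keeps
  within-trial states stable.
* **Fast noise**: small independent white noise per grid point, integrated
  with the Euler-Maruyama $\sqrt{dt}$ scaling.

### Why these states are bistable

Self-excitation ($w_{uu}$) makes detection an instability rather than a
graded response: over a band of input amplitudes both a subthreshold bump
and a self-excited suprathreshold peak are stable. The band is delimited
above by the *detection instability* (the subthreshold state is lost) and
below by the *reverse detection instability* (the peak collapses).
`scan_bistability()` locates both boundaries by deterministic relaxation
from the resting state and from a pre-formed peak. With the shipped
parameters the band lies strictly inside the amplitude range 3.8–5.4 spanned
by the experiments' contrast ladder, which is what makes hysteresis possible
over that ladder.

The inhibitory field engages only for strong input: its resting level
$h_v$ is far enough below threshold that the drive from a low-contrast peak
leaves $v < 0$ (no inhibition), while the wider, stronger peak produced by a
high-contrast object pushes $v$ above threshold and suppresses the
excitatory field over a broad surround (`w_uv` is the widest kernel). This
single coupling structure yields facilitation of a nearby probe by a
low-contrast object and suppression by a high-contrast object.

## Spatial and contrast calibration

Space is measured in field units with 8 units corresponding to the reported
6.6-arcmin center-to-center object–probe distance (`arcmin_to_units()`). The
grid spans 201 points at unit spacing, comfortably containing the ±12.8
arcmin relocation window (±15.5 units) plus kernel support; relocations are
2-D uniform draws whose consecutive Euclidean distances are mapped to signed
1-D displacements reflected at the domain edges. The field is
one-dimensional because only inter-location distance enters the couplings.

Michelson contrast maps to input amplitude linearly between the anchors
0.008 → 3.8 and 0.073 → 5.4, with the reported per-experiment overrides
(low-contrast object 0.071 → 5.0, high-contrast object 0.24 → 10.0, the
delayed probe → 4.5, the bistable object 0.041 → 4.7) taking precedence
where the corresponding simulations state them. The overrides are
kept verbatim rather than harmonized with the ladder map, preserving both
sets of reported values.

## Model observer

A frame is judged visible when $u$ exceeds 0 somewhere within half an input
width of the judged stimulus' center for at least a criterion fraction
(default 0.25) of the frame's integration steps. The sustained-occupancy
rule, rather than an instantaneous maximum, keeps transient noise spikes
from counting as percepts; the exact rule is a design choice of this
package, not something the experiments constrain directly. Probe frames are
judged in the object–probe designs, object frames in the relocation designs,
and a tie at exactly $u = 0$ counts as not visible. `score_trial()` turns
the per-frame booleans into initial visibility, switch counts, and first
switch direction; `staircase_threshold()` implements the
contrast-adjustment threshold procedure of the distance experiment.

## Parameters

The shipped defaults (`default_params()`, frozen in
`inst/extdata/default_params.yaml`) are a single parameter set used for
every experiment. They were calibrated once, in a fixed order, against the
benchmarks the model is supposed to reproduce: (1) a bistable amplitude band
strictly inside 3.8–5.4; (2) an initial-detection probability of about 0.62
for a 614-ms presentation at amplitude 4.7; (3) per-relocation switch
probabilities near 0.04 in both directions; (4) facilitation by the
amplitude-5.0 object versus suppression by the amplitude-10.0 object at a
distance of 8 units. The trace and adaptation gains balance each other at
relocated sites: the trace's spread boost carries visibility across
relocations (hysteresis, bridging of blanks), while adaptation's input
weakening keeps the visible state from becoming absorbing at constant
contrast (the observed ~0.04 switch rate) and produces the asymmetric
effect of start-of-trial repetitions.

Time constants: the excitatory/inhibitory field constants (`tau_u`,
`tau_v`) are tens of milliseconds, the trace builds within a presentation
(~400 ms) and decays over ~5 s (so an 800-ms blank retains most of it),
adaptation builds over ~1.5 s of visibility and decays over ~10 s, and the
slow noise drifts over ~15 s, i.e., effectively constant within one trial
but fresh across trials.

## Numerical choices

Explicit Euler–Maruyama at `dt` = 1 ms (stable for the chosen time
constants; noise scaled by $\sqrt{dt}$); open (zero-padded) boundaries;
kernels truncated at ±3 widths and integral-normalized so discretization
does not change total coupling. The integrator skips sources with rate
below $10^{-12}$ when convolving, which is exact to double precision for
this model because the resting state sits ~30 sigmoid units below
threshold. Stationary-state relaxations stop when the per-step change falls
below $10^{-8}$ (step budget 60,000) and classify attractors by peak $u$
against 0; amplitudes where the two relaxations agree within $10^{-3}$ are
reported as monostable.

## The synthetic protocols: what they do and do not emulate

`stimulus_synth` reconstructs the ten designs exactly as specified in the experimental designs: frame
durations (614 ms first frame, 360-ms relocations, 116-ms brief frames,
107-ms probes, 614-ms blanks), the contrast ladders with one step per
relocation and variable end contrast (the modified method of limits),
start- and end-of-trial repetitions, and the randomized relocation
geometry. Two deliberate simplifications: the black flanker and the small
position marker are not modeled as field inputs (they serve as
attention/position cues, and the model has no attention mechanism), so the
baseline condition is probe-only; and the 2-D relocations enter only
through their 1-D displacement magnitudes. The generator also cannot, of
course, reproduce observer-level realities — criterion shifts, lapses,
eye movements, learning — so passing tests show that the *model dynamics*
reproduce the phenomena under the experimental stimulus schedules, not that
every aspect of the human data is captured. One known discrepancy is noted
in the tests: drawing locations uniformly from the ±12.8-arcmin window
gives a mean consecutive relocation distance of ~13.35 arcmin (the
closed-form value for uniform draws in a square), slightly below the
reported 14.3 arcmin; the generative rule is followed as stated.

## Problem sizes

The shipped analyses use 200 simulated trials per design cell (versus ~24–48
per human observer), which brings the Monte-Carlo standard error of a
proportion below ~0.035 per cell; the pseudo-subject SEM bars mirror the
n = 8 between-observer bars of the experiments and are a presentation
choice, not inference. Smaller trial counts are used in the unit tests,
which check directions and invariants rather than precise proportions.

## Worked example

```{r example, eval = FALSE}
params <- default_params()

# bistable band of the deterministic field
scan_bistability(seq(3.8, 5.4, by = 0.1), params)[c("detection_amp", "reverse_amp")]

# the constant-contrast relocation experiment
run4 <- run_experiment(4, params, n_trials_per_cell = 50, master_seed = 1)
mean(run4$results$initial_visible)          # ~0.62: initial bistability
sc <- switch_curve(run4$results)
fit_constant_switch_probability(sc[sc$initial_state == "visible", ])$p   # ~0.04

# hysteresis under the modified method of limits
run5 <- run_experiment(5, params, n_trials_per_cell = 50, master_seed = 2)
hysteresis_gap(run5$results)
```

## Known limitations

* At very low contrast the model's detection probability falls to zero,
  while human observers keep a small nonzero rate — the model has no
  guessing/lapse mechanism.
* At object–probe gaps below ~3 arcmin the object's activation peak enters
  the probe's readout window, so the staircase of the distance experiment
  floors there; the model cannot resolve separate percepts closer than
  about half an input width.
* The inhibitory surround is calibrated for the two reported object
  amplitudes (5.0 and 10.0); intermediate contrasts interpolate the
  facilitation-to-suppression transition smoothly but without experimental
  constraint.
* The exact equation forms and constants of the original formulation are
  not reproduced here; this package's equations and its calibrated
  parameter set are its own, chosen to satisfy the reported benchmarks with
  a single shared configuration.
* Line orientation, 2-D retinotopy, and eye-movement dynamics are out of
  scope.
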