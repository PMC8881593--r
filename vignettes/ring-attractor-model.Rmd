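---
title: "A connectivity-constrained ring attractor for heading estimation with online synaptic learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A connectivity-constrained ring attractor for heading estimation with online synaptic learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxcompass)
```

## The model

`cxcompass` implements a spiking model of the *Drosophila* central-complex
heading-direction circuit and the learning problem it solves: fusing
angular-velocity (AV) input with visual landmark bearings into a single
estimate of allocentric heading, while the mapping from visual features to
heading is learned online during the trajectory itself.

The network holds 141 leaky integrate-and-fire (LIF) neurons in five
populations:

* **81 ring neurons** — visually tuned inhibitory inputs.  Three landmarks
  each drive a sub-population of 27 neurons whose Gaussian receptive
  fields (sd 6.44°, centres every 10°) tile a 270° field of view centred
  on the heading.
* **18 E-PG ("compass") neurons** — 9 per hemisphere, preferred angles
  spanning the circle at 40° spacing.  The two hemispheres' tilings are
  interleaved with a half-glomerulus (±10°) offset, so the population
  codes heading at ~20° resolution.  A localized bump of E-PG activity is
  the heading estimate.
* **16 P-EN neurons** — AV input.  The right hemisphere is driven by
  counter-clockwise rotation, the left by clockwise; each P-EN excites
  E-PG one angular step (±40°) ahead in its direction, conveying the bump.
* **16 P-EG neurons** — recurrent excitation at the same angle, sustaining
  the bump.
* **10 PIntr (Δ7) neurons** — wide inhibition onto P-EN, P-EG and
  themselves (never onto E-PG), preventing runaway excitation and
  enforcing a single winner region.

All fixed weights use the block values 20 (excitatory), −15 (inhibition
onto excitatory neurons) and −20 (PIntr→PIntr).  The plastic object is the
18×81 ring→E-PG matrix `W`, constrained non-positive: ring neurons are
inhibitory, so visual input acts by *disinhibition* against a constant
excitatory E-PG bias current.

### Learning rules

Online learning uses the presynaptically-gated Hebbian rule

```
dw[n,m] = eta * r[m] * (a * c[n] + b - w[n,m])      a = 1.7e-6, b = 1.7e-4, eta = 0.29
```

with `r` the (normalised) ring activation and `c` the E-PG activation
trace.  The package also provides the error-minimising variant

```
dw[n,m] = eta * r[m] * (c[n] - beta * I[n]),        I[n] = sum_m r[m] w[n,m]
```

Both rules are exact gradient descent on their objective functions
(`hebbian_objective()`, `errmin_objective()`); the test suite verifies the
equivalence by central finite differences at 1e-6 relative tolerance.

The offline comparison optimum solves, per compass neuron, a
lasso-regularised non-negative regression of a target activity profile on
the negated ring activations, and scales the result by −0.0025
(`optimize_weights_offline()`, backed by `glmnet`).  The penalty defaults
to 5-fold *blocked* cross-validation — contiguous time folds, because
trajectory samples are serially dependent.

## Choices the sources leave open

The circuit description fixes the populations, the sign structure, the
block weights, the LIF time constant (20 ms), the timestep (1 ms), the
tuning-curve geometry, the AV anchor (250 Hz at 10 rad/s) and the
learning-rule constants.  Everything else had to be chosen; the main
choices, and why:

**Activity scales in the learning rule.** The rule's constants only make
sense if `a*c` is commensurate with `b`, which requires `c` on a
firing-rate scale (hundreds): we use the 50 ms spike trace in Hz.  `r`
must be order-1 for `eta*r` to be a stable relaxation rate: we use the
normalised tuning activation in [0, 1].  With a literal per-timestep
application of `eta = 0.29`, every active weight would fully relax within
less than a second of co-activity and the learned structure would vanish
by trial end; we therefore read the rule as a continuous-time flow and
apply `eta * learn_gain * dt` per step, with `learn_gain = 4` the unit
conversion fixed so the relaxation converges within a fraction of a
trial.

**Weight clipping.** The sources state the maximum *effective* weight is
zero.  Under the rule above, the fixed point `a*c + b` is positive for
every active channel, so clipping the stored weights each step would make
zero absorbing and erase all structure.  The simulator therefore stores
raw weights and clips only the effective weight used for current
injection; the exported update functions retain a `clip` argument
matching the stated constraint.

**Ring-to-P-EN discretisation.** Each hemisphere has one fewer P-EN/P-EG
than E-PG.  A literal glomerulus-indexed wiring leaves one ring
transition per direction without a carrier, and the bump stalls there (we
verified this directly).  We instead couple the two discretisations by
angular wedge overlap: E-PG tile nine 40° wedges, P-EN/P-EG eight 45°
wedges, and every excitatory weight is the block value scaled by the
overlap fraction of the wedges involved.  This keeps the ring
rotationally smooth with no seam.  It is the package's single biggest
reconstruction decision.

**Hemispheric offset.** With identical preferred angles in the two
hemispheres the bump moves in 40° quanta; with the anatomically observed
interleaved tiling (±10°) the quantum halves and conveyance is markedly
smoother.  The offset is split symmetrically and the PIntr grouping
mirrored between hemispheres so the network is exactly mirror-symmetric —
asymmetric variants produced a measurable rotational bias at rest.

**AV drive calibration.** The 250 Hz anchor fixes the current an isolated
P-EN receives at 10 rad/s (10.51 at threshold 1).  The bump's rotation
speed as a function of the injected current differential is an emergent
property with a recruitment dead zone and a roughly linear region; the
encoder therefore carries a measured calibration table
(`av_shift_calibration()`) mapping commanded speed to current so that the
bump rotates at the commanded speed (verified within ~10–20% over 0.3–2
rad/s in both directions).  A constant baseline current (0.85) keeps both
hemispheres' P-EN near recruitment so the differential can steer
smoothly; the exported `pen_drive()` default remains the purely rectified
zero-baseline encoding.

**Other numerical defaults.** LIF threshold 1, reset 0, refractory 2 ms;
synaptic trace 10 ms, activation/decoder trace 50 ms; global recurrent
current gain 1.6 and E-PG bias 0.95×threshold…1 (0.98), set for a stable
single bump at 150–300 Hz that persists for seconds with < 1 glomerulus
of drift; visual pathway gain 10 000, set so the offline-optimal weights
anchor the bump without extinguishing it; bump initialisation by a 100 ms
Gaussian current pulse at the true initial heading; online weights start
i.i.d. uniform on [−1e-4, 0].  All of these live in `cx_defaults()`.

## Study conditions emulated by the generators

The **rotation trial** places three landmarks at 120° spacing, 10 m from
an agent that rotates in place for 60 s under a sinusoidal AV profile
peaking at ±2 rad/s (period 20 s), sweeping the full circle several
times.  Gaussian noise (sd 0.1 rad/s) corrupts the AV signal each step,
and state noise (sd 0.1) is injected into P-EG and PIntr neurons.

The **translation trial** matches the rotation trial's steering profile
exactly — the agent drives forward at 0.2 m/s while turning under the
same ±2 rad/s sinusoid, tracing a ~12 m meander — so translation is the
only added difficulty, and heading equals the direction of motion, which
keeps path integration with known speed well posed.  Two distal landmarks
(50 m; egocentric bearing essentially position-invariant) and one
proximal landmark (2.5 m from the path centre; strong parallax) provide
the visual scene.  The printed av-only errors of the two source trials
are nearly equal, which this matched-steering design reproduces
structurally.

What the generators do *not* emulate: camera optics and occlusion, visual
feature extraction (bearings are exact up to field-of-view clipping and
optional frame dropout), correlated sensor noise, and wheel slip.
Passing tests on these trials show that the circuit-level claims hold
under idealised sensing; they do not certify performance on real sensor
streams, for which `simulate_sensor_stream()` offers an ingestion path
with frame dropout.

## Evaluation pipeline

Three configurations differ only in the plastic matrix: `av_only`
(`W = 0`), `online` (random init + Hebbian or error-minimising rule), and
`optimal` (offline lasso solution, held fixed).  Heading is decoded from
the 50 ms-filtered E-PG spike traces by population vector; position by
dead reckoning with the ground-truth speed; errors as wrapped circular
RMSE (an unwrapped variant is also reported) and mean position error as a
percentage of path length.  `run_experiment()` runs 50 seeds per
configuration, aggregates percentile-bootstrap 95% intervals (1000
resamples) and Wilcoxon rank-sum tests, and is fully reproducible from
one seed.

```{r example, eval = FALSE}
cfg <- experiment_config(trial = "rotation", n_seeds = 50)
res <- run_experiment(cfg, seed = 1)
res$aggregate
```

Problem sizes used throughout the packaged analyses: 60 s trials at 1 ms
steps (60 000 network updates per trial), 50 seeds per configuration, and
an offline fit on every 10th timestep.

## Known limitations

* The bump's speed response is noisy near the recruitment threshold;
  sustained very slow rotation (≲0.3 rad/s) is tracked poorly.  This is
  intrinsic to a 9-glomerulus spiking ring of this size.
* Our av-only heading error is bounded-oscillatory over a trial (swing
  errors partially cancel) rather than steadily accumulating; online
  learning therefore improves on av-only integration by a smaller margin
  than the source experiments report, even though the ordering
  (optimal < online < av_only on the rotation trial) and the growth of
  the learned-to-optimal weight correlation (final mean ≈ 0.34) are
  reproduced.
* The Hebbian rule's learned structure decays where presynaptic channels
  stay active while the compass is elsewhere (the `+b` relaxation); the
  error-minimising rule is provided but the headline replication uses the
  Hebbian rule, as in the source.
* Power estimation covers algorithmic computation only (neuron updates,
  spike fanout, plastic-synapse updates); no static power, sensors, or
  host communication.
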