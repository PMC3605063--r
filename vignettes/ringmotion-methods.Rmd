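---
title: "Inferring interaction rules on a ring: models, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring interaction rules on a ring: models, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmotion)
```

# The scientific problem

Small groups of animals confined to an annular (ring-shaped) arena exhibit a
transition to collective motion: as group size grows, individuals
increasingly end up circulating in a common direction. Because motion on the
ring is effectively one-dimensional, each individual's behaviour reduces to
a binary orientation - clockwise (CW) or anti-clockwise (ACW) - plus noisy
angular displacement, which makes the system an unusually clean testbed for
asking *what interaction rule produces the collective state*.

`ringmotion` implements a complete inference pipeline for this question:

1. **Orientation decoding.** Raw angular trajectories are segmented into
   binary CW/ACW orientation sequences with a two-state hidden Markov model.
2. **Model fitting.** Eleven competing interaction models are scored on the
   decoded direction-change events by Bayesian marginal likelihood,
   estimated with annealed importance sampling (AIS).
3. **Validation at the large scale.** The selected model is simulated
   forward and its distribution of final collective states is compared with
   the data by Kullback-Leibler divergence and a G-test.

A synthetic-data generator with known ground truth stands in for the
original tracking data, so the whole pipeline is exercisable end to end.

# Conventions

Positions are angles on the annulus midline in `[0, 2*pi)`; the radial
coordinate is discarded because every model depends only on angular
separations and orientations. Increasing angle is anti-clockwise, so "CW"
means decreasing angle; orientations are coded `+1` (ACW) and `-1` (CW).
The reference recording geometry is a 200 mm outer / 70 mm inner annulus
filmed at 15 Hz and down-sampled to 7.5 Hz by dropping every second frame
(`downsample(x, 2)` keeps the even-indexed frames), giving the canonical
time step `dt = 1/7.5` s and 2700-frame, 360-second trials.

# The turning-intensity models

Each model specifies a latent *turning intensity* `lambda` - the log-odds
that a focal individual reverses its orientation in one time step - mapped
to a probability by the logistic function `p = 1 / (1 + exp(-lambda))`.
Neighbours travelling opposite to the focal individual are *negative*,
same-direction neighbours *positive*.

| id | zone | positive term | memory | free parameters |
|----|------|---------------|--------|-----------------|
| Null | none            | -- | -- | -- |
| MF   | global          | -- | -- | `wNeg` |
| T    | K nearest       | -- | -- | `wNeg`, `K` |
| S1   | symmetric width R | -- | -- | `wNeg`, `R` |
| S2   | forward length R  | -- | -- | `wNeg`, `R` |
| S3   | symmetric width R | yes | -- | `wNeg`, `wPos`, `R` |
| S4   | forward length R  | yes | -- | `wNeg`, `wPos`, `R` |
| D1-D4 | as S1-S4 | as S1-S4 | yes | + `alpha` |

The baseline `lambda0` is common to all models and is *not* fitted
alongside the rest: it is pinned (a Dirac prior) at the logit of the
direction-change rate observed in single-individual recordings, where no
interaction is possible.

Markovian intensities are linear in the neighbour counts:
`lambda = lambda0 + wNeg * nNeg (+ wPos * nPos)`, with the counts taken
over the model's zone. A *symmetric* zone of extent `R` spans half-width
`R/2` on each side of the focal individual (boundary inclusive); a
*forward* zone spans `(0, R]` ahead along the heading. `wNeg` is
constrained non-negative; `wPos` is deliberately unconstrained in sign - a
negative `wPos` means aligned company *stabilises* the current direction,
and the reference parameter set for model D3 indeed carries a strongly
negative `wPos`.

## Non-Markovian memory

The D models let an interaction outlast the encounter. The package's
default dialect keeps a *per-neighbour trace*: while neighbour `j` is in
the focal's zone its trace equals its full current weight (`wNeg` or
`wPos`, re-evaluated every frame as relative orientations change); once it
leaves, the trace decays geometrically by `alpha` per step. The intensity
is `lambda0` plus the summed traces. With the reference decay
`alpha = 0.92` at 7.5 Hz the trace half-life is
`memoryHalfLife(0.92)` = `r round(memoryHalfLife(0.92), 2)` s - about one
second, long enough for individuals separated by half the arena to retain
influence on each other.

When the focal individual itself turns, its accumulated memory is erased:
the carried traces are cleared at the next step, so the intensity returns
to `lambda0` plus whatever neighbours are currently in the zone. We read
"reset to the baseline" as erasing *memory* rather than suppressing the
live zone input, for one decisive reason: it is the only reading under
which `alpha = 0` collapses the D models *exactly* onto their Markovian
S counterparts on every input, which both intuition and the package's
invariant tests demand. A literal reset that ignored current neighbours for
one step would break that memoryless limit.

An alternative *aggregate* dialect is selectable everywhere
(`dialect = "aggregate"`): a single autoregressive intensity
`lambda_t = lambda0 + alpha * (lambda_{t-1} - lambda0) + wNeg*nNeg + wPos*nPos`,
with the carried term zeroed after an own turn. It differs from the trace
dialect in how persistent company accumulates (a neighbour that stays in
the zone compounds under the aggregate form, but contributes a constant
full weight under the trace form). Both dialects satisfy the `alpha = 0`
limit exactly; the trace dialect is the default because it gives distinct,
interpretable roles to neighbours still in the zone versus departed ones.

# Likelihood

The likelihood of a parameter set is the product over trials, individuals
and steps of the Bernoulli probability of the observed outcome - turn or no
turn - with `p` computed from the *previous frame's* snapshot of all
positions and orientations. Memory states start empty at the first frame of
each trial, propagate forward, and reset after the focal's own turns. This
previous-frame convention is the natural one for observed per-frame data.
The forward simulator necessarily decides on post-move positions (below),
and this deliberate asymmetry means spatial-zone weights re-estimated from
simulator output are mildly attenuated relative to the generating values;
the memory decay and the model *ranking* are robust to it, which is what
the package's recovery tests assert.

Probabilities are clamped to `[1e-12, 1 - 1e-12]` before logs; clamp events
are counted, warned about, and required to be zero on matched
simulator-generated data. Log-probabilities use the stable forms
`log p = lambda - log(1 + e^lambda)`.

For the models whose zone has no continuous parameter (Null, MF, and the
topological model at each `K`), the likelihood depends on the data only
through the cross-tabulation of (negative-neighbour count, event), which is
computed once; each subsequent evaluation is O(N). This is what makes
thousand-chain AIS runs cheap for those models. The spatial and memory
models are evaluated by a compiled kernel over the full data. Both routes
are checked against a plain-R implementation built from the exported
per-step intensity functions.

# Priors and annealed importance sampling

Priors are deliberately plain: `wNeg ~ U[0, wMax]`,
`wPos ~ U[-wMax, wMax]`, `R ~ U(0, rMax]`, `K` discrete uniform on
`{1, ..., N-1}`, `alpha ~ U[0, 1)`, and the same prior for the same
parameter in every model so that marginal likelihoods are comparable. The
default bounds are `wMax = 5` (comfortably covering every reference
magnitude, including the D3 `wPos` of -3.59) and `rMax = 0.5` rad (the
empirical locality diagnostic confines the interaction peak well inside
half a radian; reference radii sit at 0.16-0.20 rad). Both are exposed in
`priorSpec()` and recorded in reports.

The marginal likelihood (model evidence) integrates likelihood times prior
over the free parameters. `aisLogMarginal()` estimates it with annealed
importance sampling: each of `nSamples` (default 1000) chains starts at a
prior draw and anneals through tempered targets `prior x likelihood^beta`
along the ladder `beta_k = (k/(K-1))^3` with `K = 100` rungs - cubic
because the integrand changes fastest near `beta = 0`. Each rung applies
one Metropolis sweep: a joint Gaussian proposal over the continuous
parameters with standard deviation 5% of each prior range, reflected at the
bounds (reflection preserves proposal symmetry), plus a separate +-1 step
for the discrete `K` (moves off the support are simply rejected). The log
evidence is the log-mean-exp of the accumulated weights; its Monte-Carlo
standard error comes from the normalised weight variance. The sampler seed
for each model is derived deterministically from the master seed and the
model id, so rankings are invariant to evaluation order.

Every visited sample's unnormalised posterior is tracked, and the best one
is reported as the MAP estimate - on flat priors this is simply the best
likelihood visited, which doubles as a cheap sanity bound: the evidence can
never exceed it. Evidence is computed in nats and reported alongside bits
(nats / ln 2).

# Forward simulation

`simulateTrial()` runs any of the eleven models on the ring. Initial
positions are uniform, initial orientations fair coin flips. Per step,
agents move in a fresh uniformly random order by Gaussian steps of mean
`speedMean * dt` and standard deviation `speedSd * sqrt(dt)` along their
orientation - negative draws are allowed and reproduce the occasional
backward drift seen in real tracking. After all moves, turn decisions are
drawn synchronously from the model intensity evaluated on the post-move
positions with orientations frozen at their pre-decision values; freezing
keeps the decision stage well-defined and order-free. The `sqrt(dt)`
scaling keeps displacement variance frame-rate consistent.

The default speeds, `speedMean = 0.8` rad/s and `speedSd = 0.4` rad/s, are
chosen so that a typical individual circles the arena in about 8 s and, in
combination with the one-second memory half-life, opposite-moving agents
half an arena apart still influence one another - the qualitative regime
the reference system occupies. Both are configuration knobs.

Ensembles derive per-trial seeds from a master seed by counter, so a
10 x 100 validation protocol can be split or resumed reproducibly.

# Synthetic data

`generateDataset()` overlays the simulator's exact orientation dynamics
with tracking-like observation noise: each per-frame displacement is
replaced by a Gaussian draw of magnitude `obsMu` (default 0.1 rad/frame)
and noise `obsSigma` (default 0.05 rad/frame), signed by the true
orientation, then integrated back to positions. Applying noise to
displacements rather than positions makes the HMM's emission model exactly
the observation process at matched parameters, so HMM parameter recovery is
a clean test. Group size 1 is mandatory - those trials are the HMM training
set and the source of the pinned baseline, mirroring the single-animal
treatment of the original design. The default observation noise gives a
backward-drift probability of about 2.3% per frame, comparable to hesitant
real movement, and supports decoding accuracies above 99%.

What the generator does *not* emulate: tracking identity swaps, detection
dropouts, variable speeds, radial motion, or physical collisions. Passing
recovery tests on synthetic data therefore demonstrates the inference
machinery is correct and well-calibrated, not that real animals obey any of
these models.

# Orientation decoding

The two-state HMM is symmetric by construction: emissions are mirrored
Gaussians `(+mu, sigma)` / `(-mu, sigma)` and a single switch probability
is shared by both directions, so a zero displacement is equally probable in
either state. `baumWelch()` enforces the symmetry at every M-step by
parameter tying, uses a uniform initial state distribution (no side
information), runs log-space forward-backward recursions (2700-step
sequences underflow linear-space arithmetic), and stops at relative
log-likelihood improvement below 1e-8 or 500 iterations. A collapse of
`sigma` below 1e-6 rad aborts with advice to supply more data. If the
fitted `mu` comes out negative the labels are flipped once at convergence
to honour the ACW-positive convention.

`viterbiDecode()` breaks exact ties toward the previous state
(persistence). Decoded sequences are then despiked: scanning forward,
whenever two consecutive direction changes fall closer than 1 s the
intervening segment is reverted to the preceding state, repeated to
fixpoint - the only reading of "removing" double switches that leaves a
valid binary sequence. Despiking is idempotent and guarantees surviving
changes are at least 1 s apart. States are despiked first and events
derived afterwards; training pools all single-individual trials. A decoded
record is one frame shorter than its trajectory because each state belongs
to a between-frame displacement (attributed to the interval's start frame).

# Large-scale statistics and validation

The group-level order parameter is the polarisation `|2C - n| / n`, with
`C` the clockwise count. Because small random groups are often accidentally
polarised, the *excess* polarisation subtracts the exact binomial
expectation `E|2X - n|/n`, `X ~ Bin(n, 1/2)` (0.3125 at `n = 6`). A
trial's outcome is its clockwise count averaged over the closing 10 s and
rounded half-up; the distribution of outcomes over trials is the object
compared between data and model.

`gTest()` computes `G = 2 m KL` (natural logs, `m` experimental trials)
against a chi-squared tail with `n` degrees of freedom (categories `0..n`
minus one). Simulated categories with zero mass but observed support
receive pseudo-mass `1/(2 * nSims)` before renormalisation, keeping
divergences finite for finite ensembles while leaving genuinely
incompatible models with astronomically small p-values. Calibration under
a multinomial null (m = 50, n = 6) holds the nominal 5% size within
[0.03, 0.08]. `validateModel()` runs the 10-sets-of-100 simulation
protocol, reports all ten p-values, and flags consistency when the median
exceeds 0.05 (the median is our aggregation choice; all values are
returned).

The locality diagnostic `turnFrequencyVsNearestOpponent()` bins the signed
separation to the nearest opposite-facing individual against the empirical
turn frequency at the next step. Spatial generators produce a central peak;
global ones a flat line at the baseline rate - the package's test asserts
exactly this contrast, and steps with no opposite-facing individual are
excluded by definition.

# Problem sizes used by the test suite

The suite favours exact oracles (closed forms, exhaustive enumeration,
quadrature) at small sizes and study-scale simulation where the property is
statistical: AIS-vs-quadrature agreement uses a ~200-step dataset over ten
sampler seeds; mean-field parameter recovery uses 50 six-agent 360-s
trials; model-selection recovery uses 20 replicates of 10 trials each way;
null-model behaviour uses 2000 trials; the group-size polarisation ordering
uses 500 trials at each of n = 3, 6, 12; the locality contrast uses 20
replicates of 40 trials; and the end-to-end memory-model recovery decodes
40 six-agent trials (plus 40 single-agent training trials) and fits with 64
annealing chains over 30 rungs. These sizes are the package's choices,
balancing statistical sharpness against a suite that runs in a few minutes.

# Known limitations

* The previous-frame likelihood convention versus post-move simulation
  (above) attenuates re-estimated spatial weights; rankings and the decay
  parameter are robust, point estimates of `wNeg`/`wPos` under the D models
  should be read with that in mind.
* The despiking rule can only ever remove events; genuine rapid double
  turns (rare at realistic baselines) would be smoothed away.
* AIS gives an unbiased evidence *weight* but a slightly biased log-mean;
  with very few chains on sharp posteriors the reported standard error can
  understate the error. The quadrature cross-check covers the
  single-parameter case.
* Priors are uniform boxes; if a fitted MAP sits on `rMax` or `wMax`, widen
  the box - the report records both bounds.
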