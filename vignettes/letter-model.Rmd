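---
title: "A generative via-point model of cursive letter perception and production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generative via-point model of cursive letter perception and production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphomotor)
```

## The model

`graphomotor` implements a generative Bayesian account of single-stroke
cursive handwriting in which perception and production share one internal
representation of letters: an ordered sequence of **via-points**.  A
via-point is a four-dimensional landmark (x, y, vx, vy) placed where the
horizontal or the vertical pen velocity vanishes — a vertical or
horizontal tangent of the trace — at cusps (both components vanish), and
at the stroke's start and end.  Via-points are simultaneously perceptual
(tangent extrema are geometrically salient) and motor (they are natural
boundary constraints for trajectory planning), which is what lets one
representation serve reading, writing, copying, and reading aided by
internal motor simulation.

The sequence length is capped at 16, which is ample for every
single-stroke lowercase letterform in the package.

### Perception

The perception model is deterministic: pen velocities are estimated by
finite differences (central inside, one-sided at the ends), zero
crossings of each component are located with sub-sample precision by
linear interpolation, dwells (runs of near-zero velocity) collapse to
their midpoint, near-coincident zeroes of the two components merge into a
cusp, and detections closer than `min_sep` samples (default 3) merge,
keeping the one with the smaller residual speed.  The tolerance for
"zero" is relative: 1e-3 times the robust (95th-percentile) peak speed of
the trajectory, so the extractor is insensitive to the input's units.

Via-points are then discretized: positions on 41 integer bins (0..40)
spanning a canonical writing box, velocities on 7 integer bins (-3..3).
The box is fitted **per corpus**, not per trajectory — the corpus-wide
letter height spans the box, the x scale is tied to the y scale (aspect
preserved), and the velocity scale maps the 95th percentile of via-point
speeds to the extreme bins.  Per-trajectory normalization would destroy
exactly the size and slant cues that distinguish writers.

### The letter representation

For each (writer, letter), each via-point index j, and each of the four
dimensions independently, the model keeps a categorical table: a marginal
for j = 1 and a first-order Markov transition (current bin given the same
dimension's previous bin) for j > 1.  Probabilities are **Laplace
succession laws**, (c + 1)/(n + K): uniform before any data and never
zero.  Counts are smoothed along the current-bin axis with a binomial
filter — width 9 for position dimensions, width 7 for velocity
dimensions — so that observations generalize to neighbouring bins.  The
smoothing is implemented as a normalized convolution (kernel weights
renormalized over the in-range support at the boundaries) followed by an
exact global mass rescale; this makes a uniform vector a fixed point,
spreads an interior unit count as binomial(8, k)/256, and conserves each
context's total count exactly, so the Laplace normalization is untouched.

Dimension separability and the first-order assumption are what make the
table sizes manageable: `count_free_parameters()` reproduces the full
accounting — 296,032 free parameters per subsequent via-point at first
order, against 11,885,984 at second order, 485,566,048 at third, and
597,042,141,696 for a non-separable first-order table over the joint
4-D domain.

**Sequence length.**  Letters with different via-point counts must
compete in one posterior, and a raw product of per-index terms
systematically favours shorter sequences.  The model therefore adds an
explicit Laplace-smoothed table of the via-point count N (2..16) per
(writer, letter), and scores a sequence as log P(N) plus the sum of its
per-index, per-dimension log terms.  This is a deliberate extension of
the representation; nothing else in the scoring depends on it.

### Production

Writing inverts the representation in two steps.  First a discretized
via-point sequence is drawn ancestrally: N from the length table, the
first via-point from the per-dimension marginals, then each index from
the transition tables.  Second, the continuous trajectory is generated
through the via-points by **minimum-acceleration segments**: between two
via-points the unique minimizer of the integral of squared acceleration
under position-and-velocity boundary conditions is the cubic Hermite
interpolant, evaluated per coordinate.  Segment durations follow a
distance-proportional timing policy (duration = distance / reference
speed, floored at 0.1); the whole trajectory is sampled on one uniform
time step with on average `points_per_segment` (default 20) samples per
segment and at least 5 per segment, so every landmark stays resolvable by
the extractor.

Two production details matter and were genuinely open design choices:

* **Draws use the raw empirical tables.**  Recognition always scores
  with the smoothed Laplace law, but production draws from the raw
  counts (`c/n`, uniform only in unobserved contexts).  With 40 trials
  against 41 position bins, the add-one floor alone would place roughly
  half of every dimension's draw mass on never-observed bins, and the
  binomial spread would further blur draws into neighbouring letters'
  territory; both are generalization devices for perception, not models
  of what the hand does.  With raw-count draws, written letters are read
  back correctly in ~99% of cases; with literal Laplace draws the loop
  closes for ~11%.
* **Motor-coherence projection.**  Because dimensions are sampled
  independently, a raw draw can pair, say, a leftward velocity with
  rightward movement, or emit an interior point that is an extremum of
  neither coordinate — a landmark of no trajectory.  Draws of the second
  kind are rejected and redrawn (bounded retries, derived seeds), like
  the duplicate-position degeneracies.  For the rest, each velocity
  component is re-oriented along the local position progression, zeroed
  at extrema, and capped at 2.5 x chord-slope so the cubic segments stay
  monotone between via-points (a Fritsch–Carlson-type bound); exact
  coordinate ties are resolved by a 0.25-bin nudge.  The sampled
  magnitudes — the style information — are kept.

### The effector

The simulated arm is a planar two-joint manipulator (shoulder `L1`,
forearm `L2`; defaults 0.25 m and 0.35 m, configurable — the model's
behaviour is insensitive to the exact lengths as long as the writing box
is reachable).  Inverse kinematics is the classical closed form: elbow
angle from the law of cosines with a fixed elbow branch, shoulder angle
by angle subtraction.  Joint velocities and accelerations come from the
same finite-difference scheme as pen velocities, and
`execute_accelerations()` replays them through a semi-implicit Euler
integration — the arm "writes" the letter.  A velocity-command variant is
provided; both reproduce the planned Cartesian path within integration
tolerance, which is the model's statement of **motor equivalence**:
letterforms live in workspace coordinates, not joint coordinates.

### The six tasks

All tasks share the scoring core (`sequence_log_score_all()`, computed in
log space throughout):

* `recognize_letter()` — posterior over letters; an unknown writer is
  marginalized under a uniform prior.
* `recognize_writer()` — the symmetric task.
* `recognize_joint()` — posterior over (writer, letter) pairs; its
  marginals equal the single-label posteriors exactly.
* `write_letter()` — sample, generate, optionally execute through the
  arm; deterministic per seed.
* `copy_trajectory()` — extract via-points, regenerate, no letter
  knowledge: any trace within the 16-via-point budget can be copied, and
  the copy passes through every input via-point exactly.
* `copy_letter()` — read the input under one writer, then draw a
  sequence from the posterior-weighted mixture of letter models under
  another writer: style transfer without ever committing to a letter.
* `recognize_with_simulation()` — the product of two likelihood terms:
  the perception term on the input's via-points, and a simulation term
  obtained by regenerating a trajectory through those via-points and
  re-perceiving it with the identical extractor.  Both terms stay
  unnormalized until one final normalization.

Regeneration inside copying and simulation adapts its reference speed to
the input's median sample speed, so inputs faster or slower than the
generation default are re-timed consistently with their own boundary
velocities.

Answers can be the posterior argmax (deterministic) or a seeded draw from
the posterior; the evaluation harnesses draw by default, which mimics a
response process rather than a maximum-a-posteriori readout.

## The synthetic writers

No public corpus accompanies the model, so the package ships a
first-class generator.  `default_prototypes()` defines hand-designed
via-point skeletons for the 22 single-stroke lowercase letters (i, j, t,
x need a pen lift and are excluded).  The skeletons are mutually
distinguishable and roughly letter-like, not copies of any real hand;
the tall-ascender forms l, b, h, k are deliberately confusable, and the
letter l carries a 5-point slanted allograph next to its 6-point looped
form, so allograph machinery is exercised.  Knot velocities are derived
from the local geometry with the same monotonicity caps used in
production, which guarantees (and the tests verify) that every prototype
round-trips: generating a trajectory and re-extracting recovers the
skeleton's kind pattern and positions.

`writer_style()` turns a skeleton into a hand: a slant shear
(`x' = x + (y - 20) tan(slant)`), per-axis scales, a roundness factor on
tangent speeds, Gaussian jitter at via-points (position std 0.8 grid
units, velocity std 0.08 units/time by default — enough to vary the
extracted structure occasionally, as real allography does, without
overwhelming it), and an allograph bias (0.8 on the primary variant).
The four default styles — upright, slanted (+18 deg), rounded (x-scale
1.15, roundness 1.4), cramped (-10 deg, x-scale 0.8) — were chosen to be
separable but not trivially so.

`build_corpus()` realizes the reference design: 4 styles x 22 letters x
40 trials = 3,520 trajectories, every trial's seed derived from one
corpus seed and recorded in a manifest that rebuilds the corpus
bit-identically.

**What the generator does not emulate:** pen pressure, pen lifts,
multi-stroke letters, digits, non-stationary tremor, corpus-level letter
frequency, or the idiosyncratic allography of real writers.  Passing the
package's evaluations therefore demonstrates that the pipeline recovers
structure *of the kind it models* from noisy, style-transformed data —
not that the specific published recognition percentages on the authors'
private tablet corpus would be reproduced.

## Evaluation protocols and typical numbers

`kfold_evaluate()` splits each (writer, letter) cell's 40 trials into 8
folds (35 train / 5 test), refits everything — grid included — per fold,
and draws answers from the posterior.  On the reference corpus this
yields letter recognition of about 94% with the writer known and nearly
the same with the writer marginalized; writer recognition given the
letter sits near 91%.  `novel_writer_evaluate()` (train on three styles,
test on the fourth, writer marginalized) drops to roughly 83% —
generalizing across hands is reliably harder than recognizing a known
hand, and the gap is the point, not the absolute value.  Closed-loop
production (write then read, 100 seeded draws per letter across the four
writers) recovers the intended letter in ~99% of draws.  On truncated
inputs, perception alone can misread (the committed fixture is a
30%-tail-truncated b read as f) while the simulation-aided posterior
recovers the truth; on clean inputs the two modes agree in well over 90%
of argmax answers.  All of these are computed, at these problem sizes,
by `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Tolerances: conditional tables sum to 1 within 1e-12 (exact by
  construction up to rounding); generated trajectories reproduce their
  boundary conditions exactly in floating point; CSV round-trips hold to
  1e-9.
* Ties in the posterior argmax resolve to the first label (alphabetical
  order); sampled answers are always seeded — there is no silent
  time-based seeding anywhere.
* A stationary trajectory has no usable velocity scale; the extractor
  falls back to an absolute epsilon and returns only start and end.
* More than 16 detections raise a classed error (`viapoint_overflow`)
  naming the count rather than truncating: silent truncation would
  corrupt every downstream Markov index.
* Interior truncation re-joins the two remaining parts on a uniform time
  base (the extractor requires a single uniformly sampled series); tail
  truncation is the default experimental mode.
* Unseen (writer, letter) contexts score at the uniform Laplace floor
  automatically; an untrained letter is neither favoured nor excluded.

## Known limitations

* Per-index transition tables share statistics across sequences of
  different lengths; when a letter's extraction length varies across
  trials (the letter a's bowl-right tangent and cusp are one grid unit
  apart, so jitter shifts its structure), production draws can hybridize
  structures and occasionally land on a neighbouring letter's geometry
  (a reads as q in a few percent of single-writer draws).  This is an
  honest ambiguity of the representation, of the same family as the
  l/b/h confusions in reading.
* The canonical-orientation assumption stands: inputs are expected
  upright in the writing box; no mental rotation is attempted.
* The arm model is kinematic; no dynamics, torque limits, or real-robot
  control.
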