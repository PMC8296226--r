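---
title: "Interaction-based surgical workflow segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-based surgical workflow segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orflow)
```

## The problem

An intraoperative-MRI neurosurgery passes through six phases --
Preparation, Craniotomy, Close, MRI, TR (tumor resection), and End -- and
recognizing which phase is underway from unobtrusive sensor data is a
building block for workflow analysis and resource planning in the
operating room (OR). `orflow` implements a pipeline that does this from
*staff movement alone*: ultrasonic indoor-positioning tags on the four
staff roles (surgeon, assistant nurse, scrub nurse, anesthetist) yield
trajectories; pairwise trajectory similarity quantifies who is working
with whom; and a discrete Bayesian network maps the per-phase interaction
pattern to a phase label.

The rationale for trajectory similarity rather than simple co-location is
the size of the room: in a 5.8 x 4.8 m OR everyone is always "near"
everyone, so point-wise co-occurrence counts are dominated by fake
coincidences. Sustained joint movement -- two people tracking the same
sequence of positions through time -- is a much more specific signature of
cooperation (instrument hand-offs, joint tasks at the field).

## Interaction measurement: LCSS

For two trajectories $A = a_1,\dots,a_n$ and $B = b_1,\dots,b_m$ on a
common 1 Hz grid, the longest-common-subsequence (LCSS) length is the
longest order-preserving matching such that matched points satisfy
$\lVert a_i - b_j\rVert_{xy} \le \varepsilon$ and $|i - j| \le \delta$.
The similarity is

$$ S(A, B) \;=\; \frac{\mathrm{LCSS}(A,B)}{\min(n, m)} \in [0, 1], $$

computed by the standard $O(nm)$ dynamic programme (in C++). Defaults are
$\varepsilon = 500$ mm -- roughly within-reach distance, comfortably above
the 80 mm tracking noise floor -- and $\delta = 5$ samples. Both are
explicit `lcss_params()`, not constants: the appropriate matching radius
depends on tag placement and room geometry, and the test suite sweeps
them. Normalizing by the *shorter* trajectory keeps the measure meaningful
when one member is present only briefly. An absent role has similarity 0
with everyone by convention, plus a missing flag (below). With four roles
there are $4 \times 4 = 16$ ordered interaction kinds per segment;
self-pairs are trivially 1 and excluded from modelling.

## Features and discretization

Each case is resampled to 1 Hz (at which a step distance *is* a speed in
mm/s), sliced into phase segments on half-open intervals
$[t_\mathrm{start}, t_\mathrm{end})$, and summarized as one feature row
per segment: the LCSS similarity for each of four modelled role pairs --
surgeon--scrub, assistant--surgeon, anesthetist--assistant,
assistant--scrub -- plus the phase label. Similarities are discretized
into Low / Medium / High by per-column tertiles. Two details matter:

* **Boundaries are learned on training rows only** and frozen before they
  touch validation rows; a value equal to a boundary goes to the lower
  level. This is enforced inside every holdout repetition, so no
  information leaks from validation rows into the model.
* **Absent roles**: a missing member yields an `NA` similarity. For
  *training* the row contributes the Low level (an absent person interacts
  minimally); at *classification* the attribute is omitted from the
  evidence and marginalized by exact inference, because "the tag recorded
  nothing" should not be confused with "we measured a low interaction".

## The Bayesian network

The phase label $T$ and attribute levels $A_1,\dots,A_4$ form a discrete
Bayesian network: a DAG $G$ with one conditional probability table (CPT)
per node, factorizing the joint as
$P(X_1,\dots,X_n) = \prod_i P(X_i \mid \mathrm{Parents}(X_i))$.
Everything is implemented from first principles in this package:

* **Structure learning** is greedy hill climbing from the empty graph:
  at each step every legal single-edge addition, deletion, and reversal is
  scored, and the best strictly improving move is applied. Scores are
  decomposable and cached per (node, parent set). The default score is
  BIC, $\log \hat L - \tfrac{\log N}{2} k$ with
  $k = \sum_i (r_i - 1) q_i$ free parameters; raw maximized likelihood is
  available (`score = "loglik"`) but provably prefers the complete graph,
  and AIC and BDeu (equivalent sample size 10) are provided as standard
  alternatives. Ties between moves are broken lexicographically, making
  the search fully deterministic.
* **Parameters** are (optionally Laplace-smoothed) maximum-likelihood
  CPTs, $\hat p(x \mid a) = (N(x,a) + \alpha)/(N(a) + \alpha r)$. The
  classification default is $\alpha = 1$: with 40 training rows spread
  over up to 18 parent configurations, unsmoothed tables assign
  probability zero to held-out level combinations.
* **Inference** is exact: variable elimination over dense table factors,
  with a closed-form fast path when every non-query node is observed.
  Classification takes the posterior argmax over phase states, ties broken
  by the fixed state order.

### Why the default classifier augments the structure

Generative structure scores measure joint fit, not the quality of
$P(T \mid A_1,\dots,A_4)$. On 40-row training splits with a 6-state
target, unrestricted BIC search frequently leaves one or more attributes
outside the phase node's Markov blanket; the resulting classifier silently
ignores measured interactions and performs well below naive Bayes (which
always uses all four). This is the classic failure mode that motivated
*augmented naive Bayes* classifiers: the default
`classifier_spec("bn")` therefore requires the phase as a parent of every
attribute and lets hill climbing add attribute--attribute edges on top,
so the network is never less informed than naive Bayes and can represent
inter-attribute dependence that naive Bayes cannot.
`classifier_spec(augment_target = FALSE)` restores fully unrestricted
learning, which remains the default for *structure discovery* -- the
full-data network written by `run_pipeline()`, whose learned edges are the
semantic summary of who-works-with-whom per phase.

## Validation protocol

`repeated_holdout()` repeats, 1000 times by default: draw 40 of the 83
segment rows uniformly without replacement for training (redrawing, with a
message, any split missing an entire phase), fit discretization +
structure + CPTs on those rows only, and score accuracy on the remaining
43. `compare_classifiers()` runs several classifiers over the *same*
split sequence for paired comparison. Splits are uniform by default;
`split = "stratified"` and `split = "by_case"` are available because
segments within a case are not independent and the uniform protocol
ignores that.

A subtlety the test suite documents: on a *fixed* label-permuted table
with uniform splits, mean holdout accuracy is not exactly the $1/6$
chance level -- train and validation class compositions are negatively
correlated (drawing from a finite pool), and any spurious feature--label
association in the fixed table is shared by both sides of every split.
The package's chance-level calibration therefore permutes labels afresh
in every repetition and uses stratified splits, under which the expected
accuracy of *any* classifier on a balanced table is exactly $1/6$; the
observed mean lies within 3 Monte-Carlo standard errors of it.

## The synthetic operating room

No real OR tracking data ships with the package, so `generate_dataset()`
provides a simulator whose defaults encode the study conditions the
pipeline targets:

* **Geometry**: 5800 x 4800 mm room; entrance at (4000, 0), tool table at
  (1000, 3000); role-specific activity zones (surgeon central and wide,
  assistant nurse along the bottom and tool area, anesthetist in the
  upper-right corner, scrub nurse a tight zone at the field).
* **Movement**: per role and phase, a mean-reverting walk
  $x_{t+1} = a + \phi (x_t - a) + \epsilon_t$ around the zone anchor
  ($\phi = 0.85$/s), with phase-specific speed multipliers (Preparation
  slowest, MRI fastest) and independent Gaussian measurement noise of
  sd 80 mm on every sample. Positions are clipped to the room.
* **Cooperation**: for each modelled pair and phase, rendezvous events
  arrive at rate proportional to a configured intensity $\kappa \in
  [0,1]$ (baseline 1/40 per second at $\kappa = 1$); during a
  gamma-distributed dwell (mean 20 s) both members' walks re-anchor on a
  shared waypoint. This -- joint positions at matched times -- is exactly
  what LCSS detects, so measured similarity is monotone in $\kappa$
  (Spearman $\rho > 0.9$ across intensity levels in the tests). The
  default intensity table makes surgeon--scrub cooperation high in
  Craniotomy and TR and near-absent in Preparation and End, with the
  assistant nurse supporting the sterile pair in operative phases and the
  anesthetist--assistant channel dominating Preparation and MRI.
* **Presence**: the scrub nurse is usually absent during Preparation
  (probability 0.15 of appearing) and often leaves before End; the
  anesthetist may miss End. Absences feed the missing-data path.
* **Schedule**: Preparation, Craniotomy, TR, MRI, TR, Close, End, with
  extra alternating MRI/TR segments distributed across cases so ten cases
  yield exactly 83 phase segments by default (tumor resection interleaved
  with repeated imaging). Durations are lognormal with phase-specific
  means of 3--8 minutes and CV 0.25 -- deliberately compressed relative to
  real surgeries so that a full ten-case dataset simulates in about two
  seconds; all downstream statistics operate per segment and are
  insensitive to this time scale.

Everything is a pure function of `(config, seed)`; per-case seeds derive
from the master seed by a fixed counter scheme, so case $k$ is stable
under reordering.

**What the simulator does not emulate**: collision avoidance, gait,
doors/furniture, 3-D motion (z is carried but constant), patient state,
and any correlation between phase duration and staffing. Passing tests on
synthetic data therefore demonstrate that the pipeline recovers the
structure the generator encodes -- not that a real OR would be classified
at any particular accuracy. The headline clinical accuracies of the kind
reported for real ten-case data (~0.70 for the network, ~0.68 for naive
Bayes) are properties of undeposited recordings and can only be emulated
qualitatively: on the default synthetic conditions the 40/43 x 1000
protocol gives a mean network accuracy near 0.49 against a 1/6 chance
floor, with the network and naive Bayes effectively tied -- the same
qualitative picture.

## Numerical and degenerate-input choices

* Tertile boundaries use `quantile(type = 7)`; a column with fewer than 3
  distinct values warns and assigns by value against the degenerate
  boundaries (typically everything Low).
* CPT rows for parent configurations never seen at $\alpha = 0$ are
  uniform, with a warning.
* Evidence with probability zero under the model is an error, not a NaN.
* Hill-climbing move ties are resolved lexicographically by
  (kind, from, to); the `seed` argument exists for interface stability
  but no randomness remains to consume.
* All probability tables and posteriors are checked to sum to 1 within
  1e-9 in the test suite; inference agrees with full joint enumeration to
  1e-10 on randomized networks.

## Problem sizes used by the test suite

Structure recovery uses 20 seeded runs of N = 500 rows from a five-node
ground truth (phase driving the surgeon--scrub channel, assistant--scrub
feeding it, the remaining pairs chained); parameter recovery uses
N = 5000; the LCSS oracle enumerates all monotone matchings for 100
random pairs of length at most 8; the end-to-end protocol runs the full
1000 repetitions on the 83-segment default dataset. These sizes are the
package's chosen trade-off between statistical resolution and a test
suite that runs in minutes.
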