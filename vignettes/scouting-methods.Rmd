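---
title: "Autonomous aerial crop scouting: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autonomous aerial crop scouting: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropscout)
```

# The problem

Scouting a large crop field with a battery-limited UAS forces a choice:
exhaustive coverage gives an exact health map but costs many battery
charges and a skilled operator, while partial coverage is cheap but leaves
most zones unobserved. `cropscout` implements and evaluates a middle
path: sample a fraction of the field, extrapolate the rest from spatial
structure, and steer the sampling itself toward the places where the
extrapolation is least trustworthy.

This vignette documents the models, every tunable parameter that matters,
the synthetic data the package tests itself on, and the design decisions
taken where the problem was genuinely open.

# Ground truth: ExG health labeling

Crop health is a binary proxy derived from RGB imagery. Per pixel, on
chromatic coordinates, `ExG = 2g' - r' - b'` (bounded in [-1, 2]; black
pixels return 0 by convention). A zone's score is the mean over its tile;
a zone is *unhealthy* iff its score falls below 80% of the mean score over
all zones of the field tile being labeled, with the boundary inclusive on
the healthy side (`labelField`). Two reference-frame choices are fixed
here and worth stating:

* the threshold mean is per field tile, not per multi-field dataset — the
  natural reading of "the field" at the granularity the simulator works
  at;
* the ExG formula is the canonical chromatic-coordinate form; a
  non-normalized variant (`2G - R - B` on raw values) is available via
  `normalize = FALSE` for sensitivity checks, but nothing downstream uses
  it.

The relative rule is undefined when the field-mean ExG is non-positive;
`labelField` then stops with guidance rather than guessing.

# The spatial substrate

Coordinates are 1-based `(row, col)` on a rows × cols lattice; the
default `FieldGrid()` is 32 × 42 (1344 zones of 4.3 m²). Adjacency is
8-connectivity throughout: the directional models are defined for all
eight compass neighbours, and flight moves use the same neighbourhood by
default. Since diagonal flight moves are a genuinely open choice, the
policies and path generators expose `adjacency = 8` (default) or `4`
rather than hard-coding one intent.

A flight path partitions the grid (`partitionField`) into *visible*
(visited), *neighbour* (unobserved, 8-adjacent to visible) and *unknown*
zones. Prediction windows (`extractWindow`) are odd-sized, UAS-centred,
and **clipped** at field borders — all algorithms operate on the in-bounds
subset, and the RL state encoding pads clipped positions with sentinels so
its length never varies.

# Directional predictors and the ensemble

For each direction *d*, predictor *d* answers: given the appearance of an
observed zone at offset *d* from an unobserved target, how likely is the
target healthy? Training pairs are (tile at centre + *d*, label at
centre) over all interior centres of the training fields — the literal
one-tile-per-direction reading; the models never see the full 3 × 3
context at once.

The backend is a standardized logistic regression on eight per-tile
summary features (mean/10th/90th-percentile/sd of per-pixel ExG, channel
means, green-channel sd). At desk scale this backend reaches the same
~90% single-zone accuracy regime that heavy convolutional models reach on
real corn imagery, which is the property the rest of the pipeline
depends on; the backend contract (`fit`/`predict` probability of healthy)
is small enough that a convolutional drop-in would not change any other
module. Degenerate one-class training collapses to a Laplace-smoothed
constant, so confidences are never exactly 0 or 1.

A multiply-adjacent target combines its visible neighbours by the
**arithmetic mean of probabilities** — simple and order-invariant; the
field describes this only loosely ("akin to ensemble models"), so the
mean was chosen over majority vote, and the vote variant was dropped
rather than carried as dead configuration.

Reference tiles are scored with the mean of all eight backends applied to
the tile itself: no direction is privileged, and the score is symmetric.
`nearestReference` breaks ties toward the lowest index, which keeps fills
reproducible.

# Window filling

`fillWindow` runs synchronous wavefront iterations: every zone of the
current neighbour area is predicted from the *pre-iteration* visible set,
assigned the closest-confidence reference tile, and then promoted. Batch
promotion makes the result independent of any per-zone processing order —
the sequential alternative would be order-dependent and untestable — and
gives a clean termination bound: from a visible centre, at most
⌈(w−1)/2⌉ iterations. Originally observed zones are never overwritten;
filling a filled window is the identity.

Two subtleties:

* a zone can be globally "neighbour" while having no visible neighbour
  *inside* the clipped window; the fill recomputes the partition locally,
  so such zones simply wait one ring;
* a filled zone's stored probability is the ensemble output for it, while
  its stored *features* are those of the substituted reference tile —
  subsequent rings predict from the substituted appearance, which is the
  premise that lets predictions reach arbitrarily far from the path.

# The RL policy

The state of a filled window is `(truth layer, prediction layer,
coverage)`: observed zones contribute their label, everything else the
uninformative sentinel 0.5; length 2w² + 1. Distances are plain L2 — the
retrieval literature the k-NN rule comes from gives no metric, and the
encoding is already commensurate (all coordinates live in [0, 1]).

Experience comes from simulated random flights (`buildRLDataset`): start
at a random border zone, step uniformly among unvisited flight
neighbours, relocate to the nearest unsampled zone (Chebyshev distance,
row-major ties) when stuck. Each transition records the encoded state,
the move, the realized labels of all eight surrounding zones, and the
*utility gain* — the change in filled-window accuracy against ground
truth from before to after the step, each window centred on its own
position. Gains are normalized by the dataset's maximum absolute gain to
[-1, 1]. Relocation transitions are kept (with the compass direction of
their displacement) so the dataset holds exactly one record per
transition.

Two action rules are implemented because the method's description
genuinely contains both:

* **Discrepancy rule** (`selectAction`, the default): retrieve the k = 11
  nearest records; for each candidate action, compare the mean realized
  destination label across the retrieved records with the ensemble's
  probability for that destination; fly toward the largest absolute
  disagreement. The per-action labels are read from every retrieved
  record's `nextLabels` (that is what the field exists for) rather than
  only from records that happened to take the action — with k = 11 and
  eight actions, the latter would leave most actions without votes.
* **Utility rule** (`selectActionUtility`): the mean normalized gain of
  the retrieved records that took the action (0 if none), maximized.

Both break ties in the fixed order N, NE, …, NW. The conflict between the
two rules is documented, not resolved; the discrepancy rule is the
default because it is the one stated as the final choice.

# Baselines

*Local-field RL* uses only last-zone image features (mean ExG, mean HSV
saturation, channel means) as its state and completes its map by
recursive dilation: synchronous passes in which every unlabeled zone with
labeled 8-neighbours takes their majority label. "Consensus" is read as
majority; ties go to healthy by default (`tieBreak = "unhealthy"` is the
switch), which matches the baseline's known high-positive-recall /
low-negative-recall profile. Dilation provably completes any connected
grid within rows + cols passes, and a solid unhealthy block converts more
surrounding zones than the same number of scattered seeds — the
cluster-reinforcement failure mode, asserted on constructed inputs in the
test suite.

*Random scouting* shares the whole-field extrapolation when models are
supplied (so policy and extrapolation effects separate cleanly);
*exhaustive* flies a serpentine over every zone and returns the truth;
*non-scouting* flies nothing and treats every zone as unhealthy.

# Mission, battery and economics

The battery model is reverse-engineered from the reference mission
traces: 5% drain per zone-step from 100%, recharge to 100% whenever the
level is at or below 30% after a step. This reproduces every printed cell
of both regimes (35% at exhaustive step 13, then 85/65/45 at steps
17/21/25 after the recharge; 50% at autonomous step 10 with a single
charge), which the suite regression-tests. The bookkeeping during the
recharge interlude admits other rules that match the same cells; this one
is the simplest. Relocation flights cost one drain step per zone of
Chebyshev distance — the source material is silent here, so the cost sits
in the path-to-drain conversion where it is easy to change.

Economics: $763.8/acre corn revenue and $130/acre fertilizer convert to
$0.8 and $0.1 per 4.3 m² zone (one-decimal rounding), making a missed
unhealthy zone (classified healthy, untreated, yield lost) eight times as
costly as an overtreated healthy one. Net revenue is full yield minus
crop loss on missed unhealthy zones minus treatment of every zone
classified unhealthy minus labor. Labor is charges × 0.33 h (mid-range of
a 15–25 min flight battery) at $10/h, plus $20/h for the extra skilled
worker that only exhaustive scouting needs. The published labor figures
($212 exhaustive vs $44 autonomous at 40%) cannot be re-derived from any
printed flight-time model, so they are treated as inputs and only their
4.8× ratio is checked. Runoff risk is the percentage of truly healthy
zones slated for unnecessary fertilization, `100·FN/(TP+FN)`; metrics
with zero denominators are reported as `NA`, never silently 0.

One terminology hazard is handled by keying code to semantics: the
positive class is *healthy*, a "false positive" is a truly unhealthy zone
classified healthy (it is *missed*, costing $0.8), and a "false negative"
is a truly healthy zone classified unhealthy (*overtreated*, $0.1, the
runoff event). The cost model names these events directly rather than
trusting the labels.

# The synthetic-field generator

Real corn imagery is out of scope, so the generator reproduces the two
statistical properties the method actually relies on:

* **Spatially clustered stress** (first law of geography): iid Gaussian
  noise per zone, smoothed with a Gaussian kernel of width
  `clusterScale` (default 4 zones), lowest `unhealthyFraction` quantile
  (default 30%) marked unhealthy — the realized count is exact. The
  smoothed-threshold construction was chosen over cluster-growth
  processes because its correlation length is a single controllable
  parameter. A join-count permutation test (200 shuffles) confirms the
  clustering.
* **Imperfectly separable tiles**: each tile draws a "vigor" value
  `v ~ N(mu_label, vigorSd)` (healthy 0.8, unhealthy 0.2, clipped to
  [0, 1]) and colours the tile as the interpolation between a green
  canopy tone and a soil tone, plus per-pixel noise (sd 0.05). With
  `vigorSd = 0.234` the optimal single-tile ExG threshold classifier
  lands near 90% accuracy — deliberately imperfect, because the whole
  pipeline is designed for predictors in that regime. Tiles are 32 px
  (16 px in the test suite): texture statistics, not resolution, carry
  the signal.

Unstated field statistics (unhealthy fraction, cluster size) are stated
assumptions here, with defaults of 30% and 4 zones, and are swept in
tests. What the generator does **not** emulate: real canopy texture, row
structure, tractor traces, illumination gradients, georeferencing. A
passing suite therefore shows the algorithms are correct and behave as
designed under the assumed spatial statistics — not that any particular
accuracy carries over to real imagery.

All generation is a pure function of the spec, including its seed;
train/test/reference splits use disjoint derived seeds, and reference
tiles come from fields in neither split.

# Problem sizes

The package's own experiments run at desk scale, chosen once: 16 × 16
fields with 16 px tiles, w = 7 windows, k = 11, RL datasets of a few
hundred to a few thousand records (full-scale sweeps — 1000 paths per
combination, 73k records, 32 × 42 fields, w up to 23 — are reachable
through the same APIs by changing arguments). The Monte-Carlo properties
(whole-field beats random at 40% coverage; accuracy non-decreasing in
coverage within two standard errors) use 20 synthetic fields. These sizes
are the package's choices for a reproducible default experience; every
function accepts larger values.

# Known limitations

* The RL policy's edge over random scouting on synthetic fields is real
  but modest at these field sizes; both policies grow compact visited
  regions because relocation targets the *nearest* unsampled zone.
* Fertilizer application is the only treatment modeled; yield response,
  weather, market and pest dynamics are out of scope, as is any
  hardware/latency modeling.
* The utility-gain definition compares windows centred on different
  positions; alternative definitions (fixed-frame accuracy change) would
  also be defensible.
* Reference-set substitution can propagate a misleading appearance when
  the set is small; the reference-set size is therefore a first-order
  parameter for map quality.
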