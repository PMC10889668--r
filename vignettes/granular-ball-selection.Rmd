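---
title: "Granular-ball attribute reduction for water-quality prediction: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granular-ball attribute reduction for water-quality prediction: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Routine hydrological and water-quality monitoring produces small tables —
tens of samples, a dozen or so measured variables (water level, flow,
nutrient chemistry, temperature, ...) — from which one wants to predict a
biological response such as the chlorophyll quantity of an algal phylum, a
proxy for bloom biomass. Many of the measured variables are redundant
(different gauges of the same physical driver) or irrelevant, and
distance-based predictors such as k-nearest neighbours degrade visibly when
noise dimensions are included. `hydrogb` implements two feature-selection
strategies in front of two regressors and a common evaluation harness, so
the combinations can be compared on equal terms:

* **GBRS selection** — granular-ball rough set attribute reduction driven by
  positive-region coverage (`gbrs_forward_select()`);
* **Pearson sweep** — correlation-ranked nested-subset search scored by
  cross-validated prediction error (`sweep_select()`);
* **regressors** — kNN (`knn_fit()`) and a back-propagation network
  (`mlp_train()`);
* **metrics** — RMSE, MAE, MAPE and R² (`compute_metrics()`), with
  leakage-free cross-validated pipelines (`run_method()`).

## Granular balls and the positive region

A granular ball summarises a set of samples by its center $c = \frac{1}{N}
\sum_i x_i$ and radius $r = \frac{1}{N}\sum_i \lVert x_i - c\rVert$, the mean
member-to-center Euclidean distance. Balls are grown top-down: a single ball
over all samples is recursively split in two until every ball's *purity* —
the fraction of members sharing the majority class label — reaches the
purity threshold (default 1), or the ball cannot be split. The balls then
play the role of equivalence classes of an indiscernibility relation: the
lower approximation of a decision class is the union of balls wholly inside
it, and the size of the positive region (the union of all per-class lower
approximations) is the *coverage* — how many samples live in balls that are
unanimous about the decision.

Because the decision attribute (chlorophyll) is continuous while purity
needs class labels, the target is discretised into `q = 3` quantile bins
(`discretize_target()`), used **only** inside reduction, never for
regression. Three bins keep roughly 20 samples per class at typical
monitoring sizes; `q` is configurable.

Forward selection (`gbrs_forward_select()`) then walks the condition
attributes once, in column order by default: each attribute is tentatively
added, the partition regenerated, and the attribute retained exactly when
coverage strictly increases. Ties discard the attribute. One pass is made
and rejected attributes are not retried; an ordering by descending
`|rho|` is available as a heuristic variant (`order = "pearson"`).

### Numerical and procedural choices

* **Splitting rule.** Children are seeded from the two members farthest
  apart (ties: lowest member indices) and refined by 2-means iteration, with
  point-to-center ties going to the first center. This makes partition
  generation fully deterministic, which we value over fidelity to any
  particular stochastic k-means variant: every result in the package can be
  reproduced bit-for-bit.
* **Membership is by construction.** The geometric definition of a ball
  ($\Delta(x, c_j) \le r_j$) is not used as a membership test: with
  mean-distance radii some points would fall outside every ball. Members are
  the samples routed to the ball during splitting, so balls always partition
  the universe.
* **Degenerate balls.** A ball whose member coordinates are all identical
  but whose labels conflict can never become pure; it is flagged
  unsplittable and its members are simply never covered. This is how
  genuinely indiscernible conflicting records are expressed.
* **The singleton guard.** With strict purity and `min_size = 1`, splitting
  continues down to singletons, and a singleton is trivially pure — so with
  literal counting, coverage saturates at $n$ for *any* attribute subset on
  continuous data, destroying the selection signal. During forward selection
  a pure ball therefore counts toward coverage only when it has at least two
  members (`count_singletons = FALSE`); the literal behaviour remains
  available, and is the default in `gb_coverage()` /
  `positive_region_size()` so that the identity "coverage = summed lower
  approximations" holds exactly. Even with the guard, an irrelevant
  attribute can occasionally increase guarded coverage by forming chance
  pure pairs; the strictly-greater retention rule accepts such increases, a
  known limitation on noisy targets (see *Limitations*).
* **Empty reducts.** If no attribute ever increases coverage the reduct is
  empty; downstream pipelines fall back to the full attribute set rather
  than fitting a zero-dimensional model.
* **Indices.** All attribute and sample indices are 1-based, as everywhere
  in R; reports print the same indices.

## The Pearson sweep

The Pearson coefficient is computed from population ($1/n$) moments —
the mean, covariance and standard deviation — matching the classical
definition; the $1/n$ vs $1/(n-1)$ distinction cancels in the ratio, and
`pearson_stats()` exposes the intermediate moments. The result is clamped to
$[-1, 1]$ to absorb last-bit rounding on exactly collinear pairs.

`sweep_select()` ranks attributes by $|\rho|$ with the target and evaluates
nested subsets of size $d, d-1, \dots, 1$, each scored by cross-validated
RMSE (for kNN, minimised over the $k$ grid); the lowest-scoring subset wins,
ties going to the smaller subset. **Removal direction:** one literal reading
of the procedure would delete the attributes with the *largest* coefficients
first, discarding the most label-relevant features. The default removes the
weakest ($\min |\rho|$) first, which is the conventional backward-style
ranking sweep; `drop_order = "literal"` restores the verbatim reading. Both
are documented because the choice changes which nested subsets exist.
"Accuracy" is operationalised as RMSE throughout, the quantity the
comparison tables report.

## Regressors

**kNN.** Prediction is the unweighted mean of the $k$ nearest training
targets under Euclidean distance over the condition attributes only — the
target difference printed in some statements of the distance is unknowable
at prediction time and is excluded. Distance ties break by ascending
training-sample index (a stable secondary sort key), so predictions are
well-defined and permutation-stable except under exact ties. Attributes are
min-max scaled with training-set parameters by default; the $k$ grid default
is $\{1, 3, 5, \dots, 15\}$.

**Back-propagation network.** A multi-layer perceptron — by default one
logistic hidden layer of `max(8, 2d)` units and a linear output — trained by
full-batch steepest descent on the mean squared error at learning rate 0.01
for 2000 epochs. The architecture, rate and epochs are configurable but
deliberately plain: no momentum, no adaptive step sizes. Inputs are min-max
scaled and the target is z-standardised internally (undone at prediction
time); chlorophyll quantities are $O(10^3)$ and plain gradient descent at a
fixed rate diverges on raw targets. Weight initialisation is uniform
$\pm 1/\sqrt{\text{fan-in}}$ under a fixed seed, so training is
deterministic; a non-finite loss aborts with the offending epoch named.
`mlp_gradient()` exposes the analytic back-propagated gradient, which the
test suite checks against central finite differences.

## Evaluation protocol

The original study does not state its train/test protocol, so the package
defines one: 5-fold cross-validation with balanced, seed-deterministic folds
(`make_folds()`), feature selection re-fit inside every training fold so
held-out targets are never inspected, and all out-of-fold predictions pooled
into a single metric report. MAPE excludes zero-actual samples and reports
how many were excluded (bloom records genuinely contain zeros). R² may be
negative out-of-fold. `run_method()` wires the six pipelines — kNN, PK,
GBRSK, BP, PBP, GBRSBP — and emits the feature-count-by-$k$ RMSE grid for
the kNN family, flagging the best cell; `write_report()` lays the results
out as CSV, with an integer-rounding display mode for parity with tables
that print whole numbers.

## The synthetic generator

Real monitoring tables of this kind are typically private, so
`generate_monitoring_table()` emulates their structure rather than their
values: a monthly time axis with a 12-sample seasonal sinusoid that switches
to quarterly spacing after sample 60 (the cadence change common in long
campaigns); informative attributes = phase-shifted season plus AR(1) noise
($\phi = 0.6$); redundant attributes = affine copies of informative ones
with 10% relative jitter (keeping $|\rho| > 0.9$ with their source); noise
attributes i.i.d. normal; and a target
$\text{scale} \times \exp(\eta + 0.5\,\text{season}) + \varepsilon$, clipped
at zero, where $\eta$ is a standardised linear index of the informative
attributes and $\varepsilon$ is Gaussian with standard deviation
$0.3 \times \text{scale}$. The exponential link produces the non-negative,
right-skewed, spike-prone distribution characteristic of bloom chlorophyll;
linear and threshold links are available. The default preset (68 samples,
3 + 4 + 6 attributes, scale 1000) mirrors a five-year monthly campaign with
a sparser tail.

What the generator does **not** emulate: nutrient–algae process dynamics,
measurement censoring, cross-phylum interactions, or any real covariance
structure among the drivers. Passing tests on synthetic tables therefore
demonstrate that the machinery behaves as specified under the planted
structure — not that the method will attain any particular accuracy on real
hydrological data.

## Problem sizes used by the test suite

The suite exercises each property at the smallest size that makes it
meaningful: closed-form metric checks on 2–3 element vectors; oracle
equivalence for kNN on 200 random instances up to $n = 100$, $d = 13$;
rough-set laws on 100 random fixtures of 15–40 samples; selection recovery
and method comparison on 20 replicate tables of $n = 100$ with 2 informative,
3 redundant and 5 noise attributes; gradient checks on 20 networks of 2–5
units per layer. These sizes were chosen as the package's own testing
budget and match the small-sample regime the method targets.

## Limitations

* Coverage-driven forward selection is greedy and one-pass; it can retain a
  chance-helpful noise attribute (see the singleton-guard discussion) and
  never revisits a rejected one. On tables with heavy target noise the
  selected set should be read as a useful compression, not a certified
  minimal reduct.
* Granular-ball partitioning is of little use when the sample count is close
  to the dimension; the method targets $n \gg d$ small-table regimes.
* The BP network is intentionally plain full-batch gradient descent; it is a
  baseline, not a tuned deep model.
* `k` in kNN must be chosen; the harness sweeps a grid rather than
  optimising it, and reports the whole grid so the sensitivity is visible.

## A minimal session

```{r, eval = FALSE}
library(hydrogb)

spec <- synthetic_spec(seed = 1)
tab  <- generate_monitoring_table(spec)

red <- gbrs_forward_select(tab)     # attribute reduction
red

grid <- run_method(tab, "gbrsk")    # reduction + kNN, 5-fold CV
grid
grid$metrics

write_report(grid, "gbrsk.csv")
```
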