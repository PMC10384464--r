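---
title: "Federated data-quality profiling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated data-quality profiling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdqp)
```

## The problem

Continuous patient monitoring distributes data across edge nodes — a bedside
gateway, a clinic server — and privacy, bandwidth and latency all argue for
keeping it there. But edge data degrade: sensors drift or fail, transmissions
drop cells, a whole node can go bad. Models trained or evaluated over such a
federation inherit every one of those defects, and nobody can inspect the
pooled data because pooling is exactly what federation avoids.

`fdqp` addresses this with *federated data-quality profiling*: the only
artifacts that travel are small, versioned XML documents — data-quality
profiles — describing each node's attributes, their measured statistics, and
the repair rules to apply. A server aggregates the edge profiles, eliminates
nodes whose quality falls below tolerance, ranks features across nodes, and
broadcasts back a federated profile whose rules each edge applies locally to
produce quality-enriched data.

## The data-quality profile

A profile is a tuple of:

* **Attributes** with a data type, optional domain bounds, and a weight
  $w_j \in [0,1]$; weights sum to 1 across attributes and express relative
  clinical importance (uniform $1/D$ by default).
* **Dimensions** drawn from the closed set {completeness, accuracy,
  timeliness, uniqueness, validity, consistency}.
* **Tolerances**: per-dimension minimum acceptable levels in $[0,1]$ set by
  data specialists (e.g. completeness tolerance 0.70 means a node must keep
  at least 70% of its cells).
* **Rules**: condition-to-action repair rules (below).
* **Measures**: per-attribute statistics filled in at the edges — observed
  range, mode, skewness, missing/unique/outlier fractions, coefficient of
  variation, and an MNAR flag.

A profile plays one of three roles: the **baseline** blueprint the server
broadcasts, the **edge** profile a node measures against it, and the
**federated** profile the server aggregates from the edges. Profiles carry a
version; after the first round only field-level deltas
(`diffProfiles()`/`applyDelta()`, an exact patch algebra) are exchanged.
Serialization is a fixed XML dialect (elements `Profile`, `Attribute`,
`Measures`, `Rules`, `Rule`, `FederatedFeatures`; an XSD ships under
`inst/extdata/`) with 17-significant-digit numerics, so a write/read round
trip is the identity.

One modelling note: the attribute count and the dimension *set* are kept as
separate notions (the count is always `length(attributes)`), and the
workload stub a node may attach (its configuration and real-time resource
parameters) is carried opaquely and never interpreted.

## Dimension metrics

* Completeness $= 1 - \mathrm{missing}/\mathrm{total}$.
* Timeliness $= \max(1 - \mathrm{currency}/\mathrm{volatility},\, 0)^s$,
  with currency the data's age, volatility its shelf life (same units) and
  the exponent $s > 0$ an expert-set sensitivity (default 1).
* Correctness $= 1 / (d(w, w_m) + 1)$ for a domain distance between stored
  and true value; exposed for callers that have a gold standard (the
  pipeline itself has none).
* Uniqueness $=$ distinct/total over non-missing values (the standard
  profiling convention; no canonical formula exists for the concept).
* Consistency is tracked as the per-attribute coefficient of variation
  (sample sd over |mean|), averaged over attributes for dataset-level
  reporting and mapped to $[0,1]$ as $1/(1+\overline{CV})$ in tolerance
  checks, so that "higher is better" holds for every dimension.
* Outliers: Tukey fences $[Q_1 - 1.5\,\mathrm{IQR},\, Q_3 +
  1.5\,\mathrm{IQR}]$ by default (robust and deterministic); a $|z|>3$
  alternative is available.
* Skewness: the adjusted Fisher–Pearson standardized third moment, with the
  sample (n−1) standard deviation throughout — per-edge samples are small.

All dataset-level values used for node selection are means over attributes;
a node passes a dimension when its measured value is at or **above** the
tolerance. Equality passes: the tolerance is a minimum acceptable level, and
eliminating a boundary node on float noise would be indefensible.

## The repair rule table

Rules map an attribute's measured state to an action. The defaults (every
threshold is a config key of `defaultRuleTable()`):

| id  | condition                                          | action |
|-----|----------------------------------------------------|--------|
| 2.2 | missing fraction ≥ 0.50                            | delete column |
| 2.0 | no missing cells                                   | none |
| 2.4 | MNAR flag set                                      | KNN imputation |
| 2.5 | categorical, missing < 20%                         | mode imputation |
| 2.3 | numeric, \|skew\| > 1, missing < 5%                | median imputation |
| 2.1 | numeric, missing < 20%                             | mean imputation |
| 2.6 | numeric, 20% ≤ missing < 50%                       | multiple imputation |
| 2.7 | row missing in > 50% of retained attributes        | delete rows |

Rules are matched top-down; the first match wins. Three design points:

* Median imputation is recommended only for skewed attributes with little
  missingness; a skewed attribute in the 5–20% band falls through to the
  general-purpose mean rule rather than to "no action", because leaving
  cells unrepaired would silently break the full-completeness guarantee of
  the pipeline.
* The row rule runs after column decisions (so a bad column is deleted
  wholesale rather than nibbled away row by row) but **before** imputation —
  judged on post-imputation cells it could never fire.
* MNAR (missing-not-at-random) has no observable definition, so a heuristic
  stands in: a column is flagged when its missingness indicator correlates
  (point-biserial $|r| > 0.3$) with any *other* observed attribute. Under
  MNAR the unobserved value drives its own absence, which leaves a
  footprint on correlated channels; under MCAR there is none. The detector
  therefore has power only when features are correlated — which
  physiological channels are.

KNN imputation uses Euclidean distance on z-scored numeric predictors with
donors restricted to rows with an observed target; equal distances break to
the lower row index for determinism. Missing predictor cells enter the
distance at the column mean (z = 0), so on fully observed predictors this
is plain z-scored Euclidean distance. Multiple imputation is proper
stochastic regression: residual variance drawn from its scaled inverse
chi-squared posterior, coefficients from their sampling distribution,
residual noise added, $m$ draws pooled by mean, with
$m = \max(5, \mathrm{round}(100 \cdot \mathrm{missing\ fraction}))$ — more
missingness, more imputations. Because column-wise missingness leaves
almost no fully complete row, predictors are mean-completed for the fit,
and the imputation model keeps only the 10 predictors most correlated with
the target (irrelevant mean-completed predictors otherwise attenuate the
regression).

## Federation

Edge measures aggregate per attribute: min of minima, max of maxima,
row-count-weighted means for the fraction-valued measures, skewness and CV,
weighted votes for mode and the MNAR flag (the mapping is configurable via
`aggSpec`). Each attribute also yields a missing-value indicator: 1 if its
aggregated missing fraction is below its acceptable missing tolerance
(1 − completeness tolerance), else 0. Attribute fate combines the indicator
with the weight: a heavy attribute (weight > 0.5) must be imputed
regardless; a failing attribute with insignificant weight (< 0.1) is
dropped; the rest follow the rule table. The raw-weight interpretation is
the default; with many attributes and uniform weights the "heavy" branch
is simply never taken, which is faithful to treating the thresholds as
absolute levels.

**Feature selection.** Each node scores every feature on three criteria:
the feature value (ANOVA F statistic of feature against class label on
observed cells; a binned mutual-information scorer is the alternative —
these are the two standard scorers for numeric features with a categorical
target), the outlier fraction, and the missing fraction. Criteria are
summed across nodes and ranked — feature value descending (rank 1 = most
informative), outliers and missing ascending (rank 1 = cleanest) — and the
federated feature rank is the exact integer sum of the three ranks; lower
is better. Within a criterion, ties break by feature order (stable
first-occurrence ranking), so each rank column is a permutation of 1..N;
equal federated ranks break by value rank, then outlier rank, then missing
rank. The best `featureTol` features are retained. The default
`featureTol = 20` trims only the worst-ranked channels of the standard
22-feature cohort: in data where every channel carries signal, rank
aggregation serves as a noise filter, and aggressive trimming only adds
variance to the downstream accuracy.

**The round loop.** Broadcast → edge profiling → node selection (any node
failing a dimension tolerance is eliminated, permanently) → aggregation →
feature selection → rule application at each surviving edge → similarity
evaluation. The version increments each round, the loop stops when the
federated accuracy reaches `qTol` or after `maxRounds`, and from round 2 on
only profile deltas travel. Profiling cost is linear in edges × attributes
× dimensions × rules, and feature ranking is log-linear in the feature
count; the test suite checks both as growth shapes, not wall-clock
benchmarks.

## The similarity harness

The evaluation signal is a deliberately simple patient-similarity scheme: a
Gaussian kernel $S_{ij} = \exp(-\lVert z_i - z_j\rVert^2 / 2\sigma^2)$ on
z-scored features with $\sigma$ the median pairwise distance, and a
leave-one-out most-similar-patient prediction (each row takes the label of
its most similar other row; ties to the lower index). Accuracy is the
fraction of rows whose predicted label matches their own; per-edge
accuracies federate by row-count-weighted mean. This is a harness, not a
clinical model: it is deterministic, parameter-free, and sensitive to
exactly the cell-level damage the profiler repairs. Richer
similarity-fusion models plug in behind the same accuracy interface.
`comparePrePost()` contrasts corrupted and enriched data; the corrupted
side is naively column-mean completed so its kernel is computable at all.

## The synthetic cohort

All tests run on generated data emulating a fetal-monitoring cohort's
shape: 5 edges × 425 rows, 22 numeric features, three outcome classes at
proportions 0.78/0.14/0.08 (the strong class imbalance typical of
screening data). Features are class-conditional Gaussians with base means
in U(20, 120) and standard deviations in U(1, 10) — positive,
physiological-scale values for which a coefficient of variation is
meaningful — class means displaced by 1.5 standard deviations along random
unit directions, and block-exchangeable within-class correlation 0.6 in
blocks of 5, mimicking groups of related channels (and giving the MNAR
detector something to detect). Injections: MCAR masks cells independently;
MAR makes missingness logistic in the next observed column; MNAR logistic
(slope 4) in the cell's own value; all calibrated by root-finding the
logistic intercept so the realized rate matches the target. Outlier
injection displaces a chosen fraction of cells to a fixed multiple of the
IQR beyond the nearer Tukey fence and logs every displaced cell. Node
corruption masks an exact `ceiling((severity + 0.05) * n)` cells per column
(so completeness falls below `1 − severity` by construction and the
pass/fail decision flips exactly once along a severity sweep) and adds
Gaussian noise to surviving cells. The standard scenario draws per-column
MCAR rates once from U(0.05, 0.30), applies them identically at every
edge, adds 3% outliers at scale 3, and corrupts node 3 at severity 0.4.
Every generator is a pure function of (spec, seed), with per-operator
substreams derived by hashing, so changing one injection never perturbs
another.

What the generator does *not* emulate: the real cardiotocography feature
semantics (heart-rate baselines, decelerations, histogram features), real
missingness structure, temporal dynamics, or inter-node heterogeneity
(edges are i.i.d. by design). Passing tests therefore demonstrate the
mechanics — profiling, repair, federation, selection — under controlled
damage, not clinical performance.

## Numerical choices and degenerate inputs

* Weight sums are checked to 1e-9; profile equality after text
  serialization to 1e-9 (the writer emits 17 significant digits, so round
  trips are in fact exact).
* An all-missing column is profiled as degenerate (missing fraction 1)
  rather than raising, so the rule engine can drop it.
* Zero-variance columns are excluded from z-scoring in the kernel; a mode
  tie resolves to the smallest value so profiles are invariant to row
  order.
* `uniroot` on [−50, 50] calibrates logistic missingness intercepts.
* Seeds: one master seed; operator/node/attribute substreams via a stable
  string hash below $2^{31}$.

## Problem sizes used in the checks

The shipped tests run the full pipeline at the standard scale (5 × 425 ×
22) and smaller module-level scales (2000 rows for rate-convergence checks,
10 000 labels for proportion checks, 50-seed sweeps for the stochastic
properties). These sizes were chosen so the whole suite completes in a few
minutes while keeping binomial tolerances (±0.02) meaningful.

## Known limitations

* The accuracy benefit of profiling on the synthetic cohort is real but
  modest and is dominated by corrupted-node elimination: with MCAR damage
  at 5–30%, the rule table's prescribed action for most columns is mean
  imputation — which is also the naive baseline repair — so the repaired
  and naively completed survivors differ mainly where multiple imputation
  and feature trimming act. Across 50 seeds the federated accuracy delta is
  positive on average (about +0.013) and positive in most but not quite
  all seeds; a small negative tail (worst about −0.007) remains where the
  repair-versus-naive difference is unlucky. Stronger, systematically
  structured damage (as real sensor faults produce) widens the margin.
* MNAR detection is a correlation heuristic; it cannot see MNAR in a
  channel uncorrelated with every other channel.
* Consistency checks assume attributes with nonzero means; CV is undefined
  at mean zero and such attributes are skipped in the dataset-level mean.
* The federation is simulated in-process; there is no transport,
  authentication, or asynchronous scheduling, and no privacy mechanism
  beyond the structural one of never moving data.
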