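---
title: "Evaluating and refining cluster stratifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and refining cluster stratifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratkit)
```

## The problem

A partitional clustering of a record × feature matrix — patients by gene
expression is the motivating case — assigns every record to exactly one
cluster, whether or not it fits there. Judging and repairing that assignment
needs two quantities per record: how well it fits its *own* cluster, and how
well it would fit every *other* cluster. `stratkit` computes both under a
family of interchangeable metrics and exposes four refinement operators
(split, shift, merge, exclude) that transform a stratification without ever
losing a record.

## Fit model

Clusters are summarised by their centroid, the arithmetic feature-wise mean of
the member rows. The within-cluster fit of record $r$ is
$f(r) = d(x_r, c_{g(r)})$; the between-cluster fit is the same quantity
against each other group's centroid, with the own-group cell masked.

The metric $d$ is one of five distances (Euclidean, squared Euclidean,
Manhattan, Chebyshev, Canberra) or two correlations (Pearson, Spearman with
average ranks for ties). Distances are dissimilarities — smaller is better,
$d(a,a)=0$ — while correlations are similarities in $[-1,1]$. Every decision
that needs "closest" maps through `to_dissimilarity()`: distances pass
through, correlations become $1-r \in [0,2]$. Consequences used throughout:

* sorting "best fit first" is ascending for distances and descending for
  correlations, and the two orders agree after the $1-r$ map;
* similarity and dissimilarity fits are never placed on a shared global scale
  (their ranges are incomparable); `global_scale_max` — the value all fit bars
  are drawn against — is computed per evaluation run and per orientation;
* a correlation against a zero-variance vector is undefined; it is returned
  as 0 ("no relationship") with a classed warning rather than an error, so a
  fit view always has a value for every record. Degenerate, but visible.

Canberra sums $|a_i-b_i|/(|a_i|+|b_i|)$ with $0/0$ terms contributing 0; on
the non-negative data this tool targets it coincides with the
$|a_i+b_i|$-denominator variant some libraries use.

## Clustering algorithms

* **k-means** (`run_kmeans`): Lloyd iteration with arithmetic-mean centroids.
  Only the assignment step uses the chosen metric (via the dissimilarity
  scale); under a non-Euclidean metric the mean is not that metric's own
  minimiser, so the result is a nearest-centroid fixed point rather than an
  optimum of the metric's objective — a deliberate, documented trade that
  keeps the centroid well-defined for every metric. Empty clusters are
  re-seeded from the farthest record, so exactly `k` non-empty groups return.
  Initial centroids are `k` distinct records; because single restarts of
  Lloyd's method frequently stall in poor local optima (two initial centroids
  in one well-separated blob can never migrate out), `nstart = 25` restarts
  are run and the smallest total within-cluster dissimilarity wins. All
  sampling derives from `seed`; ties in assignment go to the lowest cluster
  index.
* **Hierarchical** (`run_hierarchical` / `cut_tree`): agglomerative merging on
  the pairwise dissimilarity matrix via `stats::hclust`, linkages single /
  complete / average / ward (`ward.D2`; rejected for non-Euclidean metrics,
  whose geometry it presumes). Cutting by `k` yields exactly `k` groups;
  cutting at height `h` yields the components merged at heights $\le h$.
* **Affinity propagation** (`run_affinity_propagation`): responsibility /
  availability message passing on the similarity $s = -$dissimilarity, shared
  preference defaulting to the median off-diagonal similarity, damping 0.9 in
  $[0.5, 1)$. The cluster count emerges from the preference; each group
  contains its exemplar. A deterministic index-based jitter of relative size
  1e-12 breaks exact ties instead of a random one, keeping runs reproducible.
  If the exemplar set has not been stable for 20 sweeps within `max_iter`,
  a classed convergence warning accompanies the best-so-far result.
* **Fuzzy c-means** (`run_fuzzy_cmeans`): alternating updates of
  $u_{ij} = 1/\sum_k (d_{ij}/d_{ik})^{2/(m-1)}$ and
  $v_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m$ with Euclidean geometry,
  fuzziness $m > 1$ (default 2), tolerance 1e-6 on the membership change,
  `max_iter` 300. Rows sum to 1 at every iteration (each run retains its
  per-iteration row-sum error and objective traces as attributes). The
  membership power is computed on row-minimum-normalised squared distances so
  it cannot overflow; a record exactly coincident with a centroid receives
  crisp membership 1 there. Initialisation draws a random row-stochastic
  membership matrix from `seed`: initialising centroids at data records
  instead makes each seed record coincident with its centroid, and the crisp
  rule then locks it (the $u^m$ weights of all other records underflow), which
  contradicts the large-$m$ limit of the update. Two caveats remain at very
  large $m$: memberships approach uniform $1/k$ for the bulk of the records,
  but the alternating updates can still collapse an individual centroid onto
  a single record, whose membership is then crisp by the coincidence rule.

## Evaluation and thresholds

`default_split_thresholds()` places the split sliders at the second and third
quartile of a group's within-cluster fit distribution, with quantiles by
linear interpolation at positions $(n-1)q$ (the `type = 7` convention, fixed
here for reproducibility). For fits $(1,2,3,4)$ that is $t_1 = 2.5$,
$t_2 = 3.25$. For similarity metrics the distribution is mirrored — the
thresholds are the first and second quartile — so "good" is again the best
half and "bad" the worst quarter.

Split regions are good $f \le t_1$, ambiguous $t_1 < f \le t_2$, bad
$f > t_2$, inequalities reversed on the similarity scale; ties therefore land
in the better region. Empty regions are dropped, and the split-off groups are
first-class: subsequent fit views use their own centroids.

`membership_view()` compares weights to the display threshold inclusively
($u \ge \tau$); the default $\tau = 1/k$ is chance level — no principled
universal value exists, and chance level at least guarantees every record
clears it somewhere. A record whose maximum weight is below $\tau$ is shown in
its argmax cluster and flagged low-confidence; records above threshold in two
or more clusters are flagged shared.

## Refinement guarantees

Every operator returns a `refinement_result` whose constructor verifies
conservation: the multiset of record ids in the new groups plus the excluded
pool equals the input's. Emptied groups are dropped, never kept as zombies,
and each drop is logged in the result's operation log.

`shift_records()` iterates centroid update / nearest-centroid reassignment to
convergence (the wording "one pass vs iterate" was open; iteration matches the
k-means analogy and its fixed point is what "elements are in the closest
cluster" means), capped at `max_iter = 100`. Its `scope` argument restricts
which records may move — both the "repair only the split-off sub-clusters" and
the global reading are supported. Monotone decrease of the recorded objective
is a theorem on the squared-Euclidean scale (it is Lloyd's objective, and the
plain-Euclidean assignment rule coincides with the squared one); under other
metrics the arithmetic-mean centroid update can let the total wobble
transiently, so the cap, not the objective, guarantees termination there. The
returned assignment is in all cases a nearest-centroid fixed point, which the
tests re-verify by brute force.

`overlap_matrix()` counts shared records over the intersection of the two
stratifications' records, matching the semantics of ribbons that connect
shared patients only; fuzzy memberships are rejected (a record sitting in two
groups at once has no well-defined overlap count) — harden first. Median
survival is the smallest time with $S \le 0.5$, reported as `NA` ("not
reached") if the curve never drops that far. No statistical test is attached
to the per-group survival curves; they are context, not inference.

## Synthetic data: what it does and does not emulate

`make_blobs()` draws isotropic Gaussian clusters with centroids spaced
`separation` × `sd` apart (centroid 1 at the origin, centroid $j$ at that
distance along coordinate axis $((j-2) \bmod d)+1$, so adjacent pairs are
exactly that far apart and all pairs at least). Outliers replace a fraction of
records: they are sampled uniformly over the centroid bounding box padded by
10 sd, rejecting anything within 5 sd of a centroid — gross but in-scale
anomalies. An unbounded outlier range would make the outliers dominate any
clustering objective (k-means would prefer to spend a cluster on them rather
than separate two genuine blobs), which is not the phenomenon the exclusion
operator models. Outliers are excluded from the truth groups into a designated
pool, mirroring the exclusion semantics.

`make_overlapping()` (separation < 3 sd) returns the generating mixture's
posterior responsibilities as fuzzy truth; `make_survival()` draws exponential
event times with per-group hazards and exponential censoring whose rate is
`censor_rate/(1-censor_rate) × hazard`, making the censoring probability
exactly `censor_rate`.

These generators emulate separation, overlap, outliers and group-dependent
survival — the features the evaluation and refinement machinery acts on. They
do **not** emulate RNA-seq count distributions, feature correlation structure,
batch effects or library-size artefacts; passing tests demonstrate the
correctness of the algorithms' contracts, not robustness to real expression
noise.

## Problem sizes and numerical choices

The test and acceptance workloads use matrices up to 50 × 10 for the oracle
equivalence sweeps (to 1e-10), 150 × 20 for blob parameter recovery, 100
records for fuzzy contracts and 500 per group for survival ordering — sizes at
which every brute-force oracle is exact and fast. Tolerances elsewhere:
membership row sums to 1e-9, metric symmetry to 1e-12, FCM convergence 1e-6.
Degenerate inputs are defined rather than rejected wherever a view must stay
total: constant vectors under correlation give 0 with a warning, a singleton
group has fit 0 to itself, all-equal fits give a degenerate split
($t_1 = t_2$), an all-censored group yields a flat survival curve at 1 with a
warning.

## Limitations

* Centroids are always arithmetic means, whatever the metric — the standard
  trade for interchangeable metrics, but medoid-style summaries are out of
  scope.
* Between-cluster fits are recomputed per call rather than cached; matrices in
  the tens of thousands of records will feel it.
* No density-based clustering, no consensus clustering, and no hypothesis
  tests on the context summaries.
* The HTML report is a static rendering (heatmap, sorted fit bars with
  threshold markers, grayscale between-cluster matrix, shared/unique fuzzy
  flags); interactive adjustment belongs to a GUI, not this package.
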