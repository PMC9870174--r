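---
title: "Mining health-survey data with subject similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining health-survey data with subject similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnmine)
```

## The problem

Large categorical health surveys (thousands of respondents, on the order
of a thousand questions, severe item non-response) hide subgroup
structure that flat per-variable summaries miss. `psnmine` implements a
network-mining workflow for such data: the subjects who are positive for
a binary target of interest (for example HIV status, injecting drug use,
homelessness, or insurance status) are embedded as nodes of a similarity
network, the network is clustered, the competing network/clustering
combinations are ranked by internal validity, and the winning clusters
are profiled feature by feature. The motivating survey style is
respondent-driven sampling (RDS), a snowball design in which each
participant recruits a few peers; `min_chain_length(n, b)` =
$\log_b(n)$ gives the shortest possible recruitment chain when every
participant recruits $b$ others, the usual back-of-envelope check that
enough waves occurred for the sample to be treated as independent of its
seeds.

Because real restricted-access survey data cannot ship with the package,
a first-class synthetic generator reproduces the structural features
that matter for every stage, with known ground truth throughout.

## Pipeline stages and their parameters

### Curation

`curate_survey()` chains four steps:

1. **Missingness pruning** (`drop_sparse_features`): features observed
   on less than `min_complete_fraction` (default 0.6) of subjects are
   removed. The default mirrors the removal of features missing 40-99%
   of their values in the motivating survey.
2. **One-hot encoding** (`one_hot_encode`): multi-valued categorical
   features become one yes/no indicator per level.
3. **Skip-to-no** (`skipped_to_no`): every non-"yes" token (no, skipped,
   residual missing) maps to 0, completing the matrix.
4. **Correlation filtering** (`correlation_filter`): while any retained
   pair has $|r| >$ `threshold` (default 0.8, Pearson on the 0/1
   encoding, i.e. the phi coefficient), the member of the worst pair
   with the larger mean absolute correlation to the other features is
   dropped; ties drop the lexicographically later name. The absolute
   value is a design choice (the threshold could also be read as signed);
   a strong negative correlation carries the same multicollinearity risk
   for the downstream logistic fits, so $|r|$ is used. Target columns
   can be protected so the filter never removes them.

The chain is idempotent on its own output, and the result is asserted to
be a complete 0/1 matrix.

### Feature selection

`step_forward_select()` is a greedy wrapper: starting from the empty
set, each step adds the feature whose addition maximizes the holdout ROC
AUC of a refit linear classifier. Design choices where the methodology
is open:

* **Holdout**: a stratified 70/30 train/test split under a caller seed.
* **Classifier**: logistic regression by IRLS with a weak fixed ridge
  penalty (`lambda = 1e-3`) on the coefficients, so a finite fit exists
  under perfect separation and the fit is deterministic.
* **Ties** between equal-AUC candidates break lexicographically.
* The "all features" set is returned without search; smaller requested
  sizes are prefixes of the largest searched size (a single greedy run).

AUC follows the Mann-Whitney formulation (ties count one half). The
training-set AUC trajectory is recorded for audit; since maximum
likelihood optimizes likelihood rather than AUC, the trajectory is only
*almost* non-decreasing — dips on the order of $10^{-4}$ occur and are
tolerated by the tests.

### Network inference

All four builders operate on the positive-target submatrix
(`subset_positive`), with **subjects as nodes**. For the two lasso
methods and correlation thresholding, the subject response vectors are
the variables and the selected features act as observations; this
transposed orientation is what makes the resulting clusters groups of
*people*.

* `knn_graph` / `min_k_connected`: undirected union of each subject's
  $k$ nearest neighbours (Euclidean distance on 0/1 vectors, i.e.
  $\sqrt{\text{Hamming}}$; distance ties break by subject order). The
  pipeline uses the smallest $k$ whose union graph is connected, and
  certifies minimality by re-checking $k-1$ on every call.
* `mb_graph`: Meinshausen-Buhlmann neighbourhood selection — one lasso
  regression per node on all other nodes (delegated to glmnet's
  coordinate descent), neighbourhoods combined with the OR rule (the
  denser choice, which helps connectivity at small penalties).
  Zero-variance subject vectors get empty neighbourhoods.
* `glasso_graph` / `glasso_fit`: an in-package graphical lasso
  (block coordinate descent with soft-thresholding, implemented in
  C++), run on the subject correlation matrix; an edge is any
  off-diagonal precision entry above $10^{-8}$ in magnitude. The
  solution is validated in the tests against the KKT stationarity
  conditions ($W - S = \rho\,\mathrm{sign}(\Theta)$ on edges,
  $|W - S| \le \rho$ off them).
* `ct_graph`: edge wherever the subject correlation exceeds a
  threshold.

**Sparsity rule.** Mirroring the minimum-$k$ rule, the penalized
methods scan a 30-point logarithmic penalty path from the null penalty
(empty graph) downward and return the sparsest *connected* graph
(`sparsest_connected`); if no path point is connected (for example when
zero-variance subjects are isolated at every penalty) the densest path
point is returned with a warning flag. For correlation thresholding the
edge sets are nested in the threshold, so the sparsest connected
threshold is found exactly by binary search over the observed
correlation values rather than on a grid.

### Clustering

* `louvain_partition` / `leiden_partition`: modularity maximization at
  resolution 1, delegated to igraph under a caller seed; Leiden's
  connected-communities guarantee is asserted on every call.
* `nbr_clust`: resilience-based node-removal clustering. A resilience
  measure is (approximately) minimized over attack sets $S$:
  vertex attack tolerance
  $\mathrm{VAT}: |S| / (|V| - |S| - C_{max}(V{-}S) + 1)$
  (empty $S$ excluded — it would trivially minimize the ratio), or
  integrity $|S| + C_{max}(V{-}S)$ (empty $S$ admissible), where
  $C_{max}$ is the largest component remaining after deleting $S$.
  Candidate sets are the prefixes of a betweenness ranking, recomputed
  after each removal, capped at $\lceil n/4 \rceil$ nodes; the best
  prefix is removed and the remaining components become clusters.
  Attack-set nodes are then reassigned to the adjacent cluster sharing
  the most edges (ties: larger cluster, then lower label) — the
  methodology leaves this step open, and full-coverage partitions are
  required downstream. Disconnected input is clustered one component at
  a time. An exact exponential minimizer (`brute_force_min`, $n \le
  15$) serves as the testing oracle; the greedy value is an upper bound
  on it by construction.

A structural note observed in the benchmarks: VAT divides the attack
cost by the number of stranded nodes, so on a multi-block graph with
one cheap boundary it prefers the single cheapest cut over full
fragmentation (on 45-node 3-block graphs at $p_{in}=0.6$,
$p_{out}=0.01$, the VAT optimum typically yields 2 clusters, median
adjusted Rand index 0.56 against the 3-block truth, while Louvain,
Leiden and integrity reach 1.0). This is the measure's true minimum,
not an artifact of the greedy search; NBR-VAT cuts respect the planted
block boundaries but need not separate every block.

### Evaluation and ranking

Five internal validity indices are computed **in feature space**
(Euclidean distances on the subjects' selected-feature vectors, with
graph-derived labels): Davies-Bouldin and Hubert-Levine C (lower is
better), Silhouette, Calinski-Harabasz and Baker-Hubert $\Gamma$
(higher is better). Each index awards one point to the single best
clustering; an exact tie withholds the point (logged). The clustering
with the most points wins; points ties are broken by pairwise
index-majority comparison. Singleton clusters participate in the
indices (real partitions here contain many small clusters); degenerate
configurations (coincident centroids, zero within-cluster variance,
all-identical points) are flagged and the affected candidate is
excluded from ranking. All five indices are verified against
independently coded brute-force oracles to $10^{-10}$.

### Reporting

`profile_clusters()` tabulates, per cluster, the percentage of members
positive for each feature (features as rows, clusters as columns in the
CSV export). Clusters with fewer than `min_size = 10` members are
suppressed from human-readable output — only their sizes are reported —
so that very small groups of respondents cannot be singled out.
Annotated graphs round-trip through GraphML.

## The synthetic generator

`generate_survey()` draws subjects in planted clusters; each cluster
has its own Bernoulli profile over the binary features, its own
categorical distribution per multi-valued feature, and its own positive
probability per target. Missingness is applied independently per cell
(MCAR) — the motivating study reports only marginal missingness rates,
so the simplest consistent mechanism is used. A small "skipped" rate
contaminates observed cells. `generate_study_table()` adds 40 junk
features missing 55-97% of their values and a few duplicated columns so
curation has realistic work to do.

What the generator does **not** emulate: recruitment-chain dependence
between subjects (RDS referral trees), missingness that depends on the
answer (MNAR), and the real survey's inter-feature correlation spectrum
beyond what planted profiles induce. Passing tests therefore show that
the machinery recovers structure *of the planted kind*, not that it
would recover structure in any particular real survey.

Default study conditions (`default_study_config()`): 800 subjects in 4
planted clusters, 56 binary + 8 multi-valued core features with light
missingness, profile probabilities 0.15/0.85, and four targets whose
per-cluster positive probabilities (e.g. 0.70/0.45/0.08/0.05 for the
HIV-like target) give positive subsets of roughly 250-350 subjects —
the same order as the real targets at this reduced scale. The planted
benchmarks use 45-node 3-block graphs and 500x10 chain-precision
Gaussian samples; these sizes keep a full run of the test-suite and
acceptance script in the minutes range while leaving the statistics
stable.

## Numerical choices

* Lasso/precision "zero": $|\theta_{ij}| > 10^{-8}$ is an edge.
* glasso convergence: mean absolute change in $W$ below $10^{-5}$
  times the mean absolute off-diagonal of $S$; non-convergence within
  200 sweeps is an error, and path fits are warm-started.
* Ridge logistic: penalty $10^{-3}$, IRLS tolerance $10^{-8}$.
* All tie-breaks (kNN distances, betweenness, correlation-filter
  drops, candidate features, rank ties) are deterministic and
  documented at the function level; every stochastic step takes an
  explicit seed, and the pipeline derives per-target seeds from its
  master seed.

## Known limitations

* NBR-Clust's attack-set search is a single-process betweenness-prefix
  greedy; it is an upper bound on the exact resilience minimum and can
  miss optimal attack sets on graphs where betweenness is a poor cut
  proxy.
* VAT-driven clustering tends toward few clusters on graphs with one
  cheap cut (see above).
* The feature-selection holdout is a single split, not
  cross-validation; selected sets can vary with the split seed.
* Validity indices are computed on binary feature vectors with
  Euclidean distance; no categorical-specific distance is offered.
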