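---
title: "Methods: sparse CCA and network integration of host-microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse CCA and network integration of host-microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcca)
```

# Scope and data model

`mbcca` integrates three data layers observed on the same animals or
samples in a group-structured design (e.g. control vs. two colitis
timepoints): a 16S taxon count table, a per-organism metatranscriptomic
gene table on the RPK scale, and a host expression table. The shared
carrier is the `feature_table` (samples x features with per-sample and
per-feature metadata). Counts and RPK values must be non-negative;
normalized or log2 tables may be signed, as centred expression data
routinely is. The `value_kind` tag is advisory — no arithmetic branches
on it — but it documents what a table holds after each transformation.

# Diversity statistics

Alpha diversity uses the textbook estimators on per-sample count
vectors: Shannon entropy `-sum p_i log p_i` (natural log by default,
with a `base` argument, since conventions differ across toolchains),
Gini-Simpson `1 - sum p_i^2`, inverse Simpson `1 / sum p_i^2`, observed
richness, and the bias-corrected Chao1
`S_obs + F1 (F1 - 1) / (2 (F2 + 1))`. The +1 in the denominator keeps
the estimator defined when no doubletons are observed; with no
singletons it collapses to the observed richness, its floor.

Bray-Curtis dissimilarity is computed on the values as provided — any
normalization (e.g. rarefaction to the minimum library size) is the
caller's responsibility upstream. The degenerate 0/0 case of two empty
samples is defined as distance 0. PCoA is classical metric scaling
(`stats::cmdscale`); Bray-Curtis is non-Euclidean, so negative
eigenvalues can occur — they are reported but contribute no coordinate
axes, and explained proportions are taken over the positive part of the
spectrum.

ANOSIM ranks all pairwise distances and compares between- to
within-group mean ranks, `R = (rb - rw) / (M / 2)`; because only ranks
enter, the statistic is invariant to monotone transformation of the
distances. Significance uses the add-one permutation estimator
`p = (1 + #(R* >= R)) / (n_perm + 1)`, which is never exactly zero and
is slightly conservative — the behaviour expected of a permutation p.
The permutation draw is seeded, so runs reproduce exactly. A pairwise
mode reports both raw and BH-adjusted p-values per group pair, since the
omnibus test does not localise differences.

# Differential abundance

Each feature is tested with the Wilcoxon rank-sum test; the p-value is
exact (full enumeration) when the pooled sample size is at most 12 with
no ties, and otherwise uses the tie-corrected normal approximation with
continuity correction. This matches small-cohort practice: at five
animals per group post-normalization ties are rare and the exact test is
cheap, while larger pooled sizes are comfortably in normal-approximation
territory. A completely tied feature (all samples equal) has no
rank information and is assigned p = 1 explicitly.

One BH family is applied per comparison per data layer, mirroring how
such studies report per-comparison tables; direction is the sign of the
group-median difference, the natural effect summary for a rank test (the
test itself is direction-agnostic, so the rule is a reporting choice).

## Taxon-specific scaling

Metatranscriptomic gene abundances confound an organism's transcription
with its abundance. `taxon_scale()` renormalizes every organism's genes
within each sample to a fixed total (default 1e6, a within-organism
counts-per-million analogue), making values read as "share of this
organism's activity". The per-taxon, per-sample total equals the
constant exactly wherever the organism is present, and multiplying an
organism's raw values in a sample by any factor leaves its scaled values
unchanged — the two properties the tests pin down. Taxon labels come
from `feature_meta$taxon` or the `"gene|taxon"` composite id convention.

## DEG pattern modules

Given up/down gene sets from the day-3 and day-6 comparisons against
control, the classifier assigns: module 1 = up on day 3 only, 2 = up in
both, 3 = up on day 6 only, and 4/5/6 analogously for downregulation. A
gene up in one comparison and down in the other fits none of the six
patterns; it receives an explicit `discordant` label rather than being
silently dropped, so the output is always a partition of the input.
Up/down conflicts within the same day are rejected as input errors.

# Sparse canonical correlation analysis

The core estimator is the rank-1 penalized matrix decomposition (PMD)
applied to the column-standardized cross-product `Z = X'Y`, treating
within-set covariance as identity — the standard "diagonal" sCCA
approximation appropriate when features outnumber samples. One component
alternates

    u <- P(Z v, c_x),   v <- P(Z' u, c_y)

where `P(w, c)` soft-thresholds `w` just enough that the L2-normalized
result has L1 norm at most `c`, with the threshold found by bisection
(60 halvings of `[0, max |w|]`, final L1 slack below 1e-6). Budgets are
parameterized as a fraction `f` of the inactive bound: `c = f sqrt(p)`.
At `f = 1` the constraint is inactive (Cauchy-Schwarz) and the iteration
is plain power iteration, so the fit equals the truncated SVD of `Z` —
the oracle the tests check to 1e-6. At `c = 1` exactly one coordinate
survives (ties to the lowest index). Components after the first come
from deflating `Z <- Z - d u v'`.

Numerical choices:

* Initialization from the leading right singular vector of `Z` —
  deterministic, so the fit itself consumes no randomness; only
  permutations and cross-validation ordering are seeded.
* Convergence when either the iterates stabilise (max change below
  `tol`, default 1e-6) or the objective `d = u'Zv` stabilises; on
  near-tied data the iterates can oscillate between equal-objective
  solutions and the objective criterion ends the loop honestly. A
  non-converged fit is returned with a flag and a warning.
* Sign convention: the largest-magnitude entry of `u` is made positive
  (flipping `u` and `v` jointly), applied before any component matching.
* Zero-variance columns cannot be standardized and are dropped with a
  log message before fitting.

## Penalty tuning

The in-sample canonical correlation is non-decreasing in `f`, so
selecting the grid value with the best in-sample correlation would
always return the largest penalty fraction. Tuning therefore scores each
grid value (one shared fraction for both sides, since a single grid is
the convention this pipeline follows) by leave-one-out cross-validation:
fit on `n - 1` samples, project the held-out sample with the refit
weights, and correlate held-out x- and y-scores across all `n`
held-out positions, averaged over components. Each refit's components
are first aligned to the full-data fit by maximal |cosine| of the
concatenated weight vectors, preventing sign flips and order swaps from
cancelling the held-out correlation. Ties go to the smallest penalty —
the sparser, more interpretable model. The default grid is 20 equally
spaced fractions from 0.02 to 0.5.

## Significance and feature robustness

Component significance permutes the sample order of `Y`, refits all `K`
components at the fitted penalties, and compares canonical correlations
component-wise by position; the raw p is the add-one estimator and BH is
applied across the `K` components. Refitting under permutation (rather
than reusing fixed weights) keeps the null honest about selection
optimism. Leave-one-out extraction refits with each sample excluded,
aligns components as above, and calls a feature robust when its weight
is nonzero in at least a `retention` fraction (default 1.0) of refits;
robust sets are by construction subsets of the selected sets.

`K` defaults to `min(n - 1, 10)` in the pipeline — enough components to
cover the handful of interpretable modules such studies report, while
bounded by the sample-driven rank.

# Association networks

Within each group's samples, all feature pairs are tested with Spearman
correlation (average ranks on ties; p from the t approximation
`t = rho sqrt((n - 2) / (1 - rho^2))` at every n, the standard practice
at the 5–15 samples per group these networks are built from). An edge
requires `p < 0.05` and `rho >= 0.5`; the signed filter is the default
reading of that rule, with an absolute-value mode available because
negative associations are biologically meaningful. Edge weight is
`-log10 p` (floored at p = 1e-300 so perfect monotone pairs keep a
finite weight). Networks are simple and undirected; global properties
(density `2E / (N (N - 1))`, mean degree) are reported with each graph.

Communities come from deterministic greedy modularity maximization
(igraph fast-greedy, unweighted), with the dendrogram cut at maximal
modularity and ties resolved toward the coarser partition — so a single
clique is one community and disconnected cliques are separated. The
reported Q is the plain Newman modularity of the returned partition.
This replaces interactive GLay clustering; the meaningful surface is the
modularity value and behaviour on separable graphs, not label-for-label
agreement with a GUI plugin.

Centralities are degree, unnormalized shortest-path betweenness (each
unordered pair counted once; normalization is rank-invariant within one
network and can be applied downstream if needed), and neighborhood
connectivity (mean neighbor degree; 0 for isolated nodes). Hubs are
made explicit as: degree at least `hub_min_degree` (default 2) and
neighborhood connectivity at or above the `hub_quantile` (default 0.90)
quantile of eligible nodes, boundary ties included — a concrete version
of "high neighborhood connectivity" that is reproducible and
relabeling-invariant.

The gene-family association table restricts the (reference-group)
network to edges joining a flagged family member (e.g. aminoacyl-tRNA
synthetases) to a host gene, annotates host genes with a user-provided
two-column gene-to-GO table (no ontology traversal), drops terms
annotating 100 or more genes (broad terms dilute specificity), and
reports distinct host-gene counts and mean rho per (microbe, term).

# The synthetic-data generators

`simulate_paired_omics` draws `K` shared standard-normal latent scores
and sparse unit-norm loading columns with equal-magnitude,
random-sign entries and (while features last) disjoint supports, then
scales the signal so the population correlation of the true projections
equals the requested strength: `corr = g^2 / (g^2 + sd^2)` per side.
With zero noise the projections are exactly collinear. Equal-magnitude
loadings make support recovery unambiguous — there are no borderline
small loadings whose recovery would be a matter of luck.

`simulate_count_table` uses a log-normal/Poisson hierarchy (log-normal
feature baselines, log-normal per-sample rate noise, Poisson counts),
the simplest generative model consistent with the rank-based tests
downstream, which are insensitive to the marginal family. Planted
features multiply their non-reference group means by
`2^(+/- log2_effect)`. Defaults are the study conditions the pipeline
is aimed at: three groups (control, day 3, day 6) of five animals —
a typical induced-colitis cohort; the cohort size is not stated by the
motivating design, so five per group was fixed once as the realistic
choice. `simulate_deg_sets` emits disjoint ids populating exactly the
requested Venn regions of the two-comparison up/down diagram.

What the generators deliberately do not emulate: phylogenetic
correlation among taxa, compositional (closed-sum) structure,
overdispersion beyond the log-normal mixing, batch effects, and
read-level error. Passing tests therefore demonstrate correctness of
the estimators and calibration under clean sampling assumptions, not
robustness to every artefact of real sequencing data.

# Validation problem sizes

The test suite validates, among others: the SVD limit on 30-sample,
50/60-feature instances; two-component recovery (n = 200, 200 features
per side, 10 nonzeros, strengths 0.9/0.7, unit noise, penalty fraction
`sqrt(10/200)` — the budget that exactly covers a planted support of 10
equal-magnitude loadings) with median sign-aligned cosines over 10
seeds; permutation calibration on 200 independent 30 x 30 datasets with
99 permutations; ANOSIM size on 500 null replicates; Wilcoxon against
full enumeration for every tie-free configuration with pooled n up to 8;
and centralities against brute-force path counting exhaustively on all
labeled 4- and 5-node graphs plus sampled 6-node graphs. These sizes
were chosen as the smallest at which the Monte-Carlo bands are
meaningful; all are fixed in the tests.

# Known limitations

* The diagonal-covariance approximation ignores within-set correlation;
  strongly collinear features share credit arbitrarily within a
  component.
* Permutation significance compares components by estimation order,
  which is the convention but can mispair components whose null
  correlations cross.
* The Spearman edge p-values use the t approximation even at small n;
  exact enumeration is used only as a test oracle. Edge-level p-values
  are not multiplicity-adjusted (the rho threshold, not the p threshold,
  is the binding filter in practice).
* `taxon_scale` makes within-organism shares comparable but removes
  organism-level abundance information by design; pair it with the taxon
  table when both matter.
* Hub calls depend on the chosen quantile; 0.90 is a reporting default,
  not an inferential threshold.
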