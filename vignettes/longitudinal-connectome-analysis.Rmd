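---
title: "Longitudinal weighted connectome analysis with longconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal weighted connectome analysis with longconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longconn)
library(dplyr)
```

## The analysis problem

`longconn` implements a complete analysis chain for longitudinal studies of
weighted brain networks in a two-group, repeated-measures design: a patient
group scanned before and after an intervention (here: three timepoints —
baseline, 1 month, 6 months) against a healthy control group scanned on the
same schedule. Each scan yields two 90-node networks on an anatomical
parcellation (AAL-90 convention): a *functional* network of pairwise Pearson
correlations between regional BOLD time courses, and a *structural* network
of streamline-count weights from diffusion tractography. The package starts
at matrices (or ROI time series); image preprocessing, tractography and
registration are upstream and out of scope.

The questions the chain answers, in order: How is each network organised
(topology metrics, small-worldness)? How tightly does function track
structure in each subject (FC–SC coupling)? Which nodes differ between
groups, and do they change over time (group × time inference)? Do metric
changes track clinical changes (change-score correlations)? And would the
findings replicate in half the cohort (split-half reproducibility)?

## Network model and topology metrics

All metrics operate on a `weighted_network`: a symmetric nonnegative weight
matrix with zero diagonal. An edge's *length* is the reciprocal of its
weight, so strong connections are short, and the shortest path length
$L_{ij}$ is the minimum over paths of summed reciprocal weights.

The package computes, per node: strength $S_i = \sum_j w_{ij}$; efficiency
$E_i = \frac{1}{N-1}\sum_{j\neq i} 1/L_{ij}$; and shortest-path betweenness
$B_i$ with its normalized form $b_i = B_i / \langle B \rangle$. Per network:
total strength $S_{net} = \frac{1}{N}\sum_i S_i$ (note this is the *mean*
nodal strength — the quantity is often described in words as a "sum", but
the defining formula carries the $1/N$ factor and the formula is what is
computed); and the characteristic path length in harmonic-mean form,

$$L_{net} = \left[ \frac{1}{N(N-1)} \sum_i \sum_{j \neq i} \frac{1}{L_{ij}} \right]^{-1}.$$

The harmonic mean is the load-bearing numerical choice here: thresholded
networks can be disconnected, and an arithmetic mean of path lengths would
be infinite. Unreachable pairs contribute $1/L_{ij} = 0$, so $L_{net}$ and
$E_i$ remain finite for any network with at least one edge. An edgeless
network returns `Inf` by convention.

Betweenness counts each unordered node pair once, with equally short paths
sharing credit fractionally (Brandes' accumulation). Because reciprocal
weights routinely create exactly representable ties (e.g. $1/0.25 = 2 + 2$),
path-length comparisons use a relative tolerance of `1e-12` rather than
exact floating-point equality. When the mean raw betweenness is zero — a
complete graph routes nothing through intermediates — all $b_i$ are set to
zero rather than erroring, since complete graphs are legal inputs.

Small-world indices compare weighted clustering $C$ (geometric-mean
triangle form, Onnela's formula, since the metric set needs *some* weighted
clustering and this is the standard choice) and $L_{net}$ against a null
ensemble: $\gamma = C/\langle C_{null}\rangle$, $\lambda =
L/\langle L_{null}\rangle$, $\sigma = \gamma/\lambda$. The null model
rewires the binarized topology with degree-preserving double-edge swaps
(10 swap attempts per edge) and reassigns the original weights in random
order — degree sequence and weight multiset are preserved exactly,
clustering structure is destroyed. 100 nulls by default; the ensemble is
deterministic given its seed.

## Thresholding

Raw matrices are reduced to a fixed *connection density*: exactly
$\mathrm{round}(d \cdot N(N-1)/2)$ strongest edges are retained with their
weights (half-up rounding; base R's banker's rounding would make edge
counts non-monotone in $d$). Ties in weight break by the fixed
upper-triangle edge order, which makes thresholding deterministic,
idempotent, and the edge sets nested along a density sweep. Density grids
default to the ranges conventionally explored for each modality —
functional 0.05–0.20, structural 0.05–0.15, step 0.01 — and downstream
metrics are typically averaged across the sweep (the AUC summary in
`metric_auc()`) to avoid privileging one density.

Negative functional correlations are set to zero before thresholding: the
path-length machinery requires nonnegative weights. The signed matrix is
retained in the `connectivity_matrix` object for edge-level analyses. No
Fisher-z transform is applied before thresholding — it is rank-preserving,
hence a no-op for density-based edge selection.

## FC–SC coupling

Per subject and timepoint: the nonzero structural edges are extracted (in
the fixed edge order), their weights are mapped to standard-normal
quantiles by rank (`qnorm((r - 0.375)/(m + 0.25))`, Blom's offset, average
ranks for ties), and the coupling score is the Pearson correlation between
those normal scores and the *raw, signed* functional values at the same
edges. Only the structural vector is Gaussianised: streamline counts are
heavily right-skewed, while correlations already live on a bounded scale.
The transform makes coupling invariant to any strictly increasing
re-weighting of the structural matrix — a deliberate robustness property,
verified in the tests. Coupling uses the raw (unthresholded) structural
matrix; thresholding before coupling would entangle the coupling score
with the density choice.

## Group × time inference

The omnibus test for every metric is a mixed-design two-way
repeated-measures ANOVA: group (between, 2 levels) × time (within, 3
levels), on completers only — missing cells are rejected, not imputed. The
implementation is the classical weighted-means sums-of-squares
decomposition with the between-subject stratum (subjects within groups)
testing group and the subject × time stratum testing time and the
interaction. For a complete within-subject design the strata decompose
orthogonally, so the sums of squares are exactly additive (a tested
invariant), and with balanced groups the results coincide with any
textbook formulation. With unequal groups (the design's 21 vs 17) this is
the Type-I (group-first) decomposition, which matches base R's
`aov(y ~ group*time + Error(subject))` — the cross-check used in the test
suite. No sphericity correction is applied to the reported p values (three
within levels); the Greenhouse–Geisser epsilon is computed and stored on
the fitted object for inspection.

Nodal families are corrected with the false-positive adjustment: the
per-test threshold is $1/n$ for a family of $n$ tests, i.e. $1/90 = .011$
for a 90-node parcellation — the expected number of false positives across
the family is then at most one. Post-hoc unpacking of flagged effects uses
pooled-variance two-sample t-tests between groups at each timepoint
(pooled, so that $t^2 = F$ against the one-way ANOVA, a tested identity)
and one-way repeated-measures ANOVAs across time within each group.
Post-hoc p values are reported raw, alongside the family threshold.

Change-score correlations are plain Pearson correlations between
per-subject deltas (e.g. change in coupling vs change in hemoglobin from
baseline to 1 month), thresholded at $p < .05$.

The permutation test for global metrics is two-sided on the absolute
difference of group means. The observed labelling counts in both numerator
and denominator, so $p$ is never exactly zero. When the number of distinct
label reassignments is at most 50,000 the test enumerates them all and is
exact (this covers every split-half comparison at the design's cohort
sizes); otherwise it draws `n_perm` (default 10,000) random reassignments
from a mandatory seed.

## Split-half reproducibility

Each cohort at each timepoint is randomly halved, redrawn (up to 1000
tries) until the halves are matched on age and education (two-sample
t-test $p > .05$) and sex (chi-square, or Fisher's exact test when any
expected cell is below 5, $p > .05$). Edge-wise mean networks of the two
halves — on unthresholded matrices — are compared by the Pearson
correlation of their upper-triangle weight vectors, and per-subject global
metrics ($S_{net}$, $L_{net}$ at a reference density, default 0.10) are
compared by the permutation test. Halvings are redrawn independently per
timepoint. One caveat worth stating: under the null of a homogeneous
cohort the permutation p value is uniform, so any single split has a 5%
chance of showing a "significant" metric difference at $\alpha = .05$; the
pattern correlation, not the permutation p, carries most of the evidential
weight.

## What the synthetic generator emulates — and what it does not

`generate_study()` builds a complete study the analysis chain can be
validated on: 21 patients and 17 controls (the design's cohort sizes) over
three timepoints, 90 nodes.

* **Structural substrate**: one small-world network shared by the cohort —
  a ring lattice at exact target density (0.15 by default, within the
  structural range), its last partially filled distance ring spread evenly
  so no node systematically carries extra degree, then 10% of edges passed
  through degree-preserving swaps to create long-range shortcuts. Lognormal
  edge weights (sdlog 0.5, a realistic right skew for streamline counts).
  The substrate's $\sigma$ is comfortably above 1 (a tested property).
* **Subject structural matrices**: substrate weights under multiplicative
  lognormal noise — a per-subject component (sdlog 0.25) stable across
  timepoints, which is what makes the repeated measures correlate, and a
  per-scan component (sdlog 0.10).
* **The planted effect**: in patients, edges incident to 5 affected nodes
  are multiplied by `deficit_scale` (default 0.5) at baseline; the deficit
  is linearly released at follow-ups by `recovery_fractions` (default 0.5
  then 0.8) — partial by construction, never 1.0, so patient trajectories
  rise monotonically toward, but never reach, the control level.
* **Functional matrices**: at structural edges, a mix of the
  rank-Gaussianised subject structural weights and independent noise in
  proportion `coupling_strength : 1 − coupling_strength` (default 0.6,
  which realises coupling scores around 0.8); at structurally unconnected
  pairs, the same mix built on the rank-Gaussianised *two-step* structural
  path strength — indirect anatomical routes support organised functional
  connectivity, and this stable backbone is what gives mean functional
  networks their reproducible pattern. The whole matrix is linearly
  rescaled into (−1, 1); being linear, the rescaling changes no
  correlation-based quantity, and at `coupling_strength = 1` the coupling
  score is exactly 1 — a tested identity.
* **Covariates and clinical course**: age, sex, education per subject, and
  a hemoglobin-like variable (g/L) that starts anaemic in patients and
  rises over follow-up while controls stay flat — giving the change-score
  analysis a real signal.

Everything derives deterministically from one seed (per-subject and
per-scan sub-seeds are hashed from it), so an identical configuration
reproduces the study bit for bit.

What passing tests on this generator do **not** show: the generator makes
no attempt at biophysical realism — no hemodynamics, no tractography
biases, no distance-dependent connection probability, no hub structure
beyond what the lattice provides, and measurement noise that is
edge-independent where real scan noise is spatially correlated. Results on
synthetic studies validate the *statistical machinery* (calibration, power
at planted effect sizes, reproducibility behaviour), not claims about any
real clinical population.

One subtlety the generator exposes: because the substrate's lognormal
weights are fixed for a cohort, any small node subset has a weighted-degree
offset from the rest (SD around 7% for 5 of 90 nodes). "Affected and
unaffected nodes are equivalent in controls" therefore holds *in
expectation over generator draws*, and the corresponding test averages the
ratio across replicate studies rather than asserting it within one.

## Numerical choices and degenerate inputs

* Shortest-path tie detection: relative tolerance `1e-12`.
* Matrix symmetry on input: relative tolerance `1e-8`; worse asymmetry is
  an error naming the worst cell. Nonzero diagonals are zeroed with a
  warning.
* Matrix files are written with 17 significant digits and parsed with
  `strtod`, so write/read round trips are bit-exact.
* Zero-variance data (a metric constant across all subjects, e.g.
  betweenness identically zero at a node) make F undefined; the fitted
  model errors with a typed condition, and the pipeline records such nodes
  as `NA` rather than failing the run. A within-group time factor with *no*
  time variation at all returns $F = 0$, $p = 1$ by convention.
* Coupling needs at least 3 nonzero structural edges and non-degenerate
  ranks; both are typed errors.
* All stochastic stages (null ensembles, permutations, splits, the
  generator) require an explicit seed and restore the caller's RNG state.

## Problem sizes used in validation

The test suite and acceptance script size their simulations to the study
design: oracle comparisons run on 100 random graphs of up to 8 nodes
(exhaustive path enumeration is exponential, and up to 8 nodes the oracle
is both fast and exercises multi-path ties); ANOVA calibration uses 5,000
null replicates at 21/17 subjects × 3 timepoints; parameter recovery uses
10 replicate full-size studies; reproducibility uses the 17-subject control
cohort. These sizes give Monte-Carlo error well inside the asserted bounds
while keeping a full run in tens of seconds.

## Known limitations

* Betweenness runs in pure R (Brandes over Dijkstra); on 90-node networks
  it costs ~0.1 s per network, which is fine for study-sized sweeps but
  would be the first thing to move to compiled code for much larger
  parcellations.
* The Type-I/weighted-means ANOVA decomposition is one of several
  defensible conventions under group imbalance; software using Type-III
  marginal tests will differ slightly for the time and interaction effects
  (never for the group effect, with a single between factor).
* The false-positive adjustment controls the *expected count* of false
  positives, not the family-wise error rate; it is deliberately the
  lightest of the standard corrections.
* Split-half balance testing accepts the first covariate-balanced halving;
  it does not search for the most balanced one.
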