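---
title: "Consensus Hamiltonian-path pseudotime: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus Hamiltonian-path pseudotime: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hamiltime)
```

## The model and its assumptions

`hamiltime` treats pseudotime inference as a family of open Hamiltonian
path problems. Two assumptions carry the whole construction:

* cells of the same type or stage are more similar to each other than to
  cells of other stages, so a short path through expression space tends to
  traverse stages in order;
* the underlying process is (locally) linear and directional. A branching
  lineage is not modelled by the path itself — each individual path
  linearizes it — but branches reappear in the *ensemble* of paths, which
  is why the transition-matrix embedding exists.

Directionality is encoded in the edge costs. Expression profiles are
smoothed with a pseudocount (default `1e-6`), normalized to the probability
simplex, and compared with the Kullback–Leibler divergence in nats,
`sum(p * log(p/q))`. KL is asymmetric: moving from a concentrated profile
to a diffuse one is cheaper than the reverse, which gives the path search a
mild preference for a consistent direction of differentiation. The
logarithm base is irrelevant to any ordering (a positive rescaling of all
costs), so nats are used. Because expression vectors are not distributions,
the pseudocount-simplex construction is a modelling contract of this
package, not a property of the data; the pseudocount is exposed and its
exact value is immaterial over several orders of magnitude (it only guards
`log(0)`).

## Clustering representation

For each granularity k the cells are clustered once per dataset by
average-linkage hierarchical clustering and the dendrogram is cut at k.
The clustering does not operate on raw expression but on the
double-centered Spearman representation: pairwise Spearman dissimilarity
`D = (1 - rho)/2`, element-squared, then the classical MDS operator
`B = -1/2 J D^2 J`. Rank-based distances make the clustering invariant to
any strictly monotone per-cell distortion; double centering converts
distances to a Gram-like form whose rows are usable as Euclidean features.
Note the printed form of the distance used elsewhere, `(rho + 1)/2`, is a
similarity; a dissimilarity is required for clustering, so the reflected
convention is the default and the similarity is available as
`convention = "as_printed"`.

Cluster centroids are arithmetic means of member rows of the *original*
log-expression, because KL costs must be computed on expression-like
nonnegative vectors, not on the centered representation.

## The insertion heuristic

The path solver is a modified arbitrary-insertion construction that works
directly on directed costs:

* **Seeding.** Each restart seeds the path with a directed pair (a, b)
  sampled from the `top_q = 10` largest off-diagonal costs. Two far-apart
  nodes tend to be the true endpoints of an open path, and seeding with
  them avoids the pathology of insertion heuristics that grow from a
  central pair. The published description of this method's endpoint
  initialization is not publicly available in detail; this endpoint-spread
  rule is this package's own concrete design, validated against the
  exhaustive oracle in the test suite.
* **Insertion.** Remaining nodes are inserted in random order at the
  position minimizing the directed insertion cost
  `d(u, v) + d(v, w) - d(u, w)` for interior slots and `d(v, head)` /
  `d(tail, v)` at the ends. No symmetrization is applied anywhere.
* **Restarts.** The best of `restarts = 10` randomized constructions wins;
  ties break lexicographically so results are reproducible for a fixed
  seed.

On 200 random Euclidean instances with n = 7 the heuristic attains the
exhaustive optimum in 194 (97%), and it can never beat it — both facts are
regression-tested against `brute_force_path()`, an independent n! oracle
guarded to n ≤ 9.

## Consensus construction

Per-cell scores from the base granularities k = 3..7 are merged by an
exhaustive orientation search: each of the 2^5 = 32 keep/reflect
assignments is scored by the sum of its 10 pairwise Spearman correlations,
the best assignment is kept, and the oriented vectors are averaged. The
search is genuinely enumerative and the counters (`n_assignments`,
`n_pairwise`) are exposed on the result for verification. Spearman is used
throughout the orientation logic (the merge stage is rank-based by
definition, and using one correlation everywhere keeps the two stages
consistent).

Later paths, k = 7..N, are oriented against the current reference and
folded in by a running mean. The weighting is not prescribed anywhere
authoritative, so the simplest equal-weight reading is used: the reference
enters with weight 5 (its five base paths) and every later k contributes
weight 1. k = 7 deliberately appears in both the base set and the merge
stream, matching the method's published defaults literally; both ranges are
user-configurable.

The global direction of the final pseudotime is arbitrary — reflecting
every input path reflects the output. If the user names a root cell, the
output is reflected so that cell scores below 0.5; otherwise the
`direction_anchor` field says the direction is arbitrary, and the
evaluation metrics are direction-free.

## Transition matrix and branch detection

Every path contributes unit mass per consecutive node pair; cluster-level
edges split their unit mass uniformly over member-cell pairs so large
clusters do not dominate, keeping total mass equal to the number of edges
contributed. The embedding is PCA of the symmetrized, **row-normalized**
matrix. Row normalization is the one default that deserves emphasis: the
raw symmetrized count matrix has localized, bump-like rows whose PCA
spectrum is nearly flat, making PC1 an arbitrary parity mode (measured
Spearman with the true order ≈ 0.5 on a linear fixture); normalizing rows
to transition probability distributions concentrates variance in the
low-frequency gradient and PC1 then tracks the order (≈ 0.94 on the same
fixture) while branch arms separate cleanly. Note the idealized case of a
*single* path repeated verbatim still has a width-1 band matrix with tied
mirror modes and no meaningful PC1; the embedding is informative exactly
because the consensus contains paths at many granularities.

## Gene dynamics

dCor and MIC both detect non-monotone dependence on [0, 1] scales, which
suits genes that switch rather than drift. dCor is the exact sample
statistic via double-centered distance matrices, cross-checked to 1e-10
against a direct-summation oracle. MIC here is an equal-frequency-grid
search: all grid shapes with `nx * ny <= n^0.6` (at most 15 bins per axis)
are evaluated and the normalized mutual information is maximized. This is
a deliberate simplification of the original dynamic-programming partition
optimization: it is exact on noiseless monotone relationships (every
equal-frequency grid of a monotone map is a bijection between bins, so the
normalized MI is 1) and conservative elsewhere; for ranking genes against
a pseudotime this bias is acceptable and the null behaviour (mean MIC
< 0.3 on independent data at n = 200) is tested. A gene is kept when
`max(dCor, MIC) >= 0.5` by default; the threshold is a parameter because
different analyses legitimately use different stringencies (0.5 for broad
screens, higher for focused module work).

The per-gene HMM has 2 (optionally 3) Gaussian states initialized from the
sorted expression values split into equal blocks — an initialization that
brackets the on/off means without EM getting trapped at a single mode.
By default Baum–Welch re-estimates transition probabilities only, treating
the block-based emissions as fixed scales ("the transition probability is
inferred" is the published phrasing; full re-estimation is available via
`update_emissions`). The EM log-likelihood is asserted non-decreasing at
every iteration, and Viterbi decoding is verified against exhaustive
2^L enumeration for all test sequences with L ≤ 12. Degenerate inputs are
handled explicitly: constant genes yield a flagged single-state track, and
zero-variance blocks floor the emission sd at 1e-3.

## G0 detection

Cells are summarized by six phase-list means (G1, S, G1/S, G2, M, G2/M,
e.g. Cyclebase-derived lists supplied by the user), partitioned by k-means
with k = 5 (one slot per canonical phase plus G0), and the cluster with the
lowest grand mean is tested against every other cluster on every score —
24 one-sided Welch tests, all of which must reach P < 0.001. No
multiple-testing correction is applied: the criterion is deliberately a
raw-P conjunction, which is already very conservative (any single
non-significant comparison vetoes the call). "Pairwise ANOVA" with two
groups is algebraically a pooled-variance t-test; the one-sided Welch test
is the default because the hypothesis is directional (candidate *lower*)
and cluster variances differ; `classic_anova` restores the literal
two-sided F-test, and `pooled` compares against all remaining cells at
once.

A known limitation, demonstrated in the test suite: when the data contain
fewer than five real populations, the forced k = 5 over-partitions —
k-means' global optimum may split the quiescent pool itself, the candidate
then fails significance against its own twin, and the report is (by
design) empty. This failure is conservative (no false G0 calls) and
disappears when the cluster granularity matches the populations; the
conjunction rule trades recall for precision deliberately.

## Evaluation metrics

Two printed formulas required correction to satisfy their own stated
endpoints, and both package defaults implement the corrected forms:
CI = 1 − (s − ns + 1)/(N − ns) (the widely circulated variant with
"− ns − 1" exceeds 1 at a perfect ordering and is available as
`as_printed`), and BI = 1 − s/S (the bare ratio s/S would score a perfect
ordering 0). POS is the signed pair-concordance and satisfies
POS = 2·BI − 1 identically, an identity the tests assert. KC is Kendall
tau-b; note tau-b against tied stage labels has a ceiling below 1
(`sqrt((n0 − n2)/n0)`), so KC ≈ 0.82 on the standard fixture corresponds
to a near-perfect ordering, as the simultaneous BI/POS ≈ 0.999 show.
All metrics evaluate both the ordering and its reverse and report the
better, because consensus direction is arbitrary.

## What the synthetic fixtures do and do not show

`simulate_linear()` (defaults: 150 cells, 3 equal quantile stages, 300
genes of which 30% monotone, 30% switch-like, 40% stationary noise,
Gaussian noise sd 0.5 on the log scale, thresholded dropout at probability
0.2 below level 2) generates the statistical structure the method assumes:
stage-monotone and switch-like signals on a log scale with additive noise
and dropout zeros. The defaults were chosen once as a realistic
middle ground for a few-hundred-cell, GO-filtered working set, and sized so
the full k = 3..N sweep completes in a couple of seconds per run; all
end-to-end checks (Kendall recovery ≥ 0.8 on seeds 1–5, branch silhouette
> 0.25) run at these sizes. What the fixtures do *not* emulate: count-level
sampling noise (negative binomial), batch effects, doublets, or realistic
gene–gene correlation beyond the shared latent pseudotime. Passing these
tests therefore demonstrates correctness of the algorithms under their own
assumptions, not performance on any particular real dataset.

`simulate_branch()` adds two post-branch arms with disjoint marker
programs (the switch genes are split between arms); `simulate_cycle_scores()`
draws the six phase scores directly, bypassing expression, to test the G0
logic in isolation. All generators are pure functions of (parameters,
seed).

## Numerical choices

* Insertion/brute-force cost ties break lexicographically; path costs are
  recomputable from the cost matrix to 1e-9.
* Spearman correlations of constant vectors are undefined; they are
  treated as 0 (orientation-neutral) with a warning where user-visible.
* KL costs are clamped at 0 against floating-point negatives; diagonals
  are set to 0 exactly.
* `double_center` output is doubly centered to 1e-10 (tested).
* Min–max rescaling maps constant vectors to all-zero rather than NaN.
* All randomized entry points (`insertion_path`,
  `consensus_pseudotime`, `detect_g0`, the generators) take an explicit
  seed, save and restore the caller's RNG state, and derive per-k seeds as
  `seed + k` so every solve is independently reproducible.

## Interfaces

Dense TSV/CSV (header row, id column, either orientation) and MatrixMarket
MTX with `genes.txt`/`barcodes.txt` sidecars are read natively; gene sets
come as plain lists or GMT. Gene universes (GO development terms, cycle
phase lists) are always user-supplied inputs — ontology releases drift and
bundling one would freeze it silently. All outputs are plain TSV. The
command-line wrapper (`inst/cli/hamiltime.R`) is a thin layer over the
exported functions with subcommands `run`, `simulate`, `evaluate`, `g0`,
and `genes`.
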