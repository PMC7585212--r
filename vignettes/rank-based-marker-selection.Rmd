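---
title: "Rank-based marker selection: model, solver, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based marker selection: model, solver, and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankcorr)
```

## The model

`rankcorr` selects marker genes for a given clustering of single-cell
RNA-seq counts by looking, one cluster at a time, for a sparse hyperplane
through the origin that separates that cluster from all other cells.  Write
`X` for the n × p cells × genes count matrix and, for cluster k, `τ ∈
{±1}^n` for its one-vs-rest indicator.  We want a coefficient vector `ω`
with few nonzero entries such that `sign(X̄ω) ≈ τ`, where `X̄` is a
transformed count matrix; the nonzero coordinates of `ω` are the markers.

Two transformations make this work with a hyperplane pinned at the origin:

* every gene column is replaced by its **tie-averaged ranks**
  (`rank_vector()`), then centered and scaled to unit *population* standard
  deviation (`rank_and_standardize()`);
* the indicator `τ` is also ranked and centered
  (`center_ranked_indicator()`), which leaves the selected markers unchanged
  but makes the algebra below read as a Spearman correlation.

Ranking needs no assumptions about the count distribution and no prior
library-size normalization: it compresses the heavy right tail of UMI counts
while stretching the gap between "not detected" and "detected" (all zeros in
a column share one low averaged rank), which is exactly the contrast a
marker should carry.  It is also invariant under any strictly increasing
per-gene transformation, so scaling or log-transforming counts upstream
cannot change the result.

The relaxed selection problem is the convex program

$$\hat\omega = \arg\max_{\omega} \; \sum_i \bar\tau_i \langle \bar x_i, \omega\rangle
\quad\text{s.t.}\quad \|\omega\|_2 \le 1,\; \|\omega\|_1 \le \sqrt{s}.$$

The objective is `⟨v, ω⟩` with `v = X̄ᵀτ̄`, and `v_j / (n·σ(Φ(τ)))` is
exactly the Spearman rank correlation between gene j and `τ`
(`correlation_vector()`, `spearman_scores()`).  So the method ultimately
ranks genes by absolute Spearman correlation with cluster membership; the
optimization determines *how many* of the top genes enter, given `s`.

## The solver

The maximizer is a normalized soft-thresholding of `v`:
`ω̂ = T_β(v)/‖T_β(v)‖₂`, where `T_β` shrinks every coordinate toward zero
by β and zeroes those with `|v_j| ≤ β`.  The ratio
`f(β) = ‖T_β(v)‖₁/‖T_β(v)‖₂` is continuous and non-increasing on
`[0, max|v|)`, so the correct threshold is the root of `f(β) = √s` — the
point where the normalized solution lands on the ℓ1 sphere.
`select_support()` finds it exactly: with the top-k magnitudes active the
stopping condition is the quadratic
`k(k−s)β² − 2S₁(k−s)β + (S₁² − sS₂) = 0` (S₁, S₂ the active magnitude sums),
so we scan support sizes upward, treating tied magnitudes as one breakpoint,
until a root falls inside the corresponding interval.  No iteration, no
tolerance beyond floating point.

Numerical and degenerate-case choices:

* **Soft-threshold form.** We use the standard operator
  `sign(x)(|x| − β)₊`; it is the only form under which the support is
  `{|v_j| > β}` and the closed-form solution solves the program (a
  literal reading of some printed definitions would *grow* negative
  entries).
* **Inactive constraint.** If `‖v‖₁/‖v‖₂ ≤ √s` on the nonzeros of `v`, the
  ℓ1 constraint is slack: `β* = 0`, `ω̂ = v/‖v‖₂`, and all non-constant
  genes are reported (`constraint_active = FALSE`).
* **Tie groups.** Tied `|v|` values enter the support together.  If `s` is
  smaller than the size g of the top tie group, `f ≥ √g > √s` everywhere and
  no root exists; we return the full tie group with equal weights scaled to
  `‖ω̂‖₁ = √s` — a genuine maximizer (feasible since `‖ω̂‖₂ = √(s/g) ≤ 1`),
  and the deterministic, conservative report of a non-unique optimum.  In
  this one case `‖ω̂‖₂ < 1`.
* **Constant genes** have zero rank variance, carry no class information,
  and are dropped before selection (recorded in `dropped_genes`); a matrix
  with only constant genes is an error, not an empty result.

Because the support is always a magnitude prefix of `|v|`, supports are
nested as `s` grows — more `s`, more markers, never an exchange.  A
consequence worth knowing: at fixed `s`, the *length* of a cluster's list
depends on the shape of its correlation profile.  A flat profile (many
comparably correlated genes) reaches the ℓ1 sphere with about `s`
coordinates, while a single dominant gene needs many small companions to
accumulate ℓ1 mass, giving a longer list.  Per-cluster counts are therefore
informative but not monotone in any intuitive "difficulty" ordering; only
monotonicity in `s` is guaranteed.

The SPA-style quasi-standardization (`spa_standardize()`), which
interpolates between centered and fully standardized raw-count columns with
weights driven by each gene's Pearson correlation with `τ`, is provided as
the hyperparameterized alternative transformation; the rank transform is the
default precisely because it has no `α, λ` to tune.

## Multi-class selection

`rankcorr(X, y, s)` fixes one `s` for all clusters, computes `X̄` once,
solves the one-vs-rest program per cluster, and reports per-cluster lists
(ordered by `|ω̂|`, ties by gene index) plus their deduplicated union
(first-seen cluster order).  Duplicates across clusters are deliberately not
reconciled beyond the union — per-cluster lists keep them.  With exactly two
clusters the two problems are mirror images (`τ ↔ −τ` flips `v`'s sign but
not `|v|`), so both lists contain the same genes; this is expected, not a
bug.  The fit is a classed object with `print`, `summary`, `coef`,
`predict` (nearest-centroid classification on the marker union) and `plot`
methods.

## Evaluation protocol

Marker sets are scored by how well they let a simple learner recover the
reference clustering, under 5-fold cross-validation
(`cross_validated_evaluation()`): markers are selected and the classifier
trained on four folds, the held-out fold is classified, and classification
metrics (error, class-size-weighted precision with never-predicted classes
contributing 0, Gorodkin multi-class MCC) are computed once on the
concatenated whole-dataset predictions.  The classifier
(`train_ncc()`/`predict_ncc()`) log-normalizes counts (library size 10,000,
then `log2(1+x)` — the standard pipeline normalization, used only here,
never inside selection), restricts to the markers, and assigns each cell to
the Euclidean-nearest class centroid, ties to the lowest class id.  Cells
with zero counts pass through normalization unchanged rather than erroring;
filtering them is the caller's decision.

Unsupervised evaluation (`louvain_grid_cluster()`) builds a k-nearest-
neighbour graph directly in log-normalized marker space — no PCA, since the
markers already are the chosen dimensions — and runs Louvain community
detection (delegated to igraph behind an injectable callable) over the
resolution grid 0.1–3.0 in steps of 0.1, reporting the best ARI, AMI and
FMS separately over the grid.  Per-fold clusterings need not be compatible
across folds, so clustering metrics are computed per held-out fold and
averaged.  ARI, AMI (hypergeometric expected-MI correction, arithmetic-mean
entropy normalizer — the common modern default; the normalizer choice was
open) and the Fowlkes–Mallows score are computed in-package from the
contingency table, since no installed package provides all three; ARI is
cross-checked against an independent implementation in the tests.

Method comparison uses Average-of-Medians scores (`aom_rank()`): per method
and marker-count range, the median of each metric over the evaluated points
in the range (points only, no interpolation — medians blunt the sensitivity
to where points fall in a rapidly improving region), averaged over the
metric family, with error flipped to `1 − error` so larger is uniformly
better; ranks are per range, ties sharing the minimum rank.

## The synthetic generator

`simulate_counts()` emulates a droplet-style two-group experiment in the
Splat tradition: per-gene base means from Gamma(shape 0.3, scale 1),
per-cell library sizes from LogNormal(log 1000, 0.3), counts from a
negative binomial (gamma–Poisson, dispersion 0.5) around the cell-scaled
gene means, and **no dropout on top** — zero inflation beyond the NB is
deliberately omitted because indiscriminate zeroing is a poor model of
dropout and the NB already produces realistic sparsity.  These defaults
yield roughly 85–90% zero entries.  Differential expression follows the
Splat two-group design: exactly `round(de_fraction · p)` genes (default
10%) are flagged in group 1, each multiplied by a factor
`f ~ LogNormal(0.1, 0.4)` or its reciprocal with equal probability
(`de_up_prob` exposes the direction probability; the exact-count draw
rather than per-gene Bernoulli makes ground truth deterministic for
testing).  Many factors land near 1, so a realistic share of "DE" genes is
barely detectable — precision curves on these data are supposed to decay.

What the simulator does *not* model: mean–variance (BCV) trends, batch
effects, cell trajectories, and parameters estimated from any real tissue.
Passing recovery tests here shows the method finds multiplicatively shifted
NB genes under library-size noise; it does not certify performance on the
full complexity of experimental data.

Supporting pieces: `dispersion_filter()` (equal-occupancy mean bins,
median/MAD-standardized variance-to-mean ratio, top-n nested selection —
MAD rather than sd because dispersions within a bin are heavy-tailed),
`random_markers()` (the uniform baseline whose expected precision equals
the DE fraction), and `marker_recovery_metrics()` (precision/TPR/FPR at
every prefix, computed without cross-validation since with simulated truth
every gene is test data).

## Problem sizes and test design

The test-suite and acceptance computations run at deliberately modest sizes
chosen to exercise every contract while staying quick on one core: solver
equivalence on 200+ random instances with p ≤ 12 against an independent
convex-programming oracle (an active-set SQP, which identifies supports
sharply where first-order methods crawl along nearly tied faces); Spearman
equivalence on 100 random 15–30-cell instances; generator calibration on
600 × 1500 simulations over 10 seeds (the null screen is a Wilcoxon
rank-sum test on genes detected in ≥ 10% of cells — on rarer genes the
discrete null makes the test conservative, a property of the test, not the
generator); recovery studies on 500 × 1000 simulations with inflated effect
sizes (`de_scale = 1.5`, base means floored at 0.5) so that success is
attributable to signal rather than luck.  The same seeds always reproduce
the same datasets bit for bit.

## Known limitations

* Hyperplanes pass through the origin by construction; an intercept would
  require a different (slower) solver and is out of scope.
* `s` is a user knob: the package does not choose it, and no p-values are
  attached to markers.
* The AMI's expected-MI term is O(levels² × n) and intended for the
  evaluation scale (hundreds to thousands of cells per fold), not for
  million-cell contingency tables.
* The dense rank matrix `X̄` is materialized; for very large matrices,
  select on a subsample or filter genes first (e.g. `dispersion_filter()`).
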