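---
title: "Methods: twin-based connectome predictive modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-based connectome predictive modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twincpm)
```

## The scientific question

Resting-state functional connectivity (rsFC) predicts individual
differences in general intelligence, and both intelligence and rsFC are
partly heritable. The question this package operationalizes is sharper
than either fact alone: does the *intelligence-related part* of the
connectome generalize across co-twins, and does it do so more strongly
when the twins are genetically identical? Two complementary designs
address it.

**Cross-twin prediction.** Twin pairs are split so that one member of
every pair forms a training group and the co-twin forms the testing
group (leave-one-group-out cross-validation, LOGOCV). A model trained to
predict the G-score from the training group's edge vectors is then
evaluated on the co-twins. If intelligence-related connectivity is
shared within pairs, the model transfers; the transfer should be
stronger for monozygotic (MZ) than dizygotic (DZ) pairs.

**Within-pair difference prediction.** For each pair, the absolute
G-score difference |G_a − G_b| is regressed on the per-edge absolute
connectivity difference |x_a − x_b| under ordinary k-fold
cross-validation over pairs. This asks whether the *degree* of
intelligence similarity is encoded in the degree of connectome
similarity — whole-brain, and separately within each of ten canonical
functional networks.

Around these sit classical twin statistics (co-twin G correlations and
Falconer's h² = 2(rMZ − rDZ)), connectome fingerprinting (identifying
the co-twin as the individual with the most correlated edge vector), and
formal comparisons of the MZ and DZ prediction accuracies (Fisher z test
on independent correlations, Cohen's q, Zou's confidence interval, and a
normal-approximation power calculation).

## Data representation

An acquisition yields, per subject and run, a timepoints × R matrix of
ROI-averaged BOLD series (R = 268 for the full parcellation).
`compute_fc_matrix()` forms all pairwise Pearson correlations and maps
them to Fisher z scores (atanh); `average_runs()` averages the z
matrices over runs (four in a full acquisition; fewer is allowed with a
warning so small fixtures work). `vectorize_lower_triangle()` then takes
the strictly-lower-triangular entries — R(R−1)/2 = 35 778 unique edges at
R = 268 — as the subject's edge vector.

The edge ordering is fixed package-wide as row-major over node pairs
(i, j) with i > j: (2,1), (3,1), (3,2), (4,1), … No ordering is canonical
in the literature, so the package picks one, documents it, and provides
`edge_to_nodes()` / `nodes_to_edge()` as the bijection. The diagonal is
stored as zero and never consumed. Correlations of magnitude one (which
occur in degenerate toy data, not in BOLD) are clamped to 1 − 1e−12
before the transform, with a warning.

The atlas maps each node to one of ten networks (MFN, FPN, DMN, MOT,
VISI, VISII, VAN, LMB, BG, CRB with 29/28/18/49/18/9/18/30/29/40 nodes
at R = 268). The published node-to-network assignment is not
redistributable, so `canonical_atlas()` assigns contiguous blocks with
the canonical sizes — a synthetic ordering that preserves everything the
network-level operations depend on (sizes and membership structure), not
node anatomy. `scaled_atlas(R)` allocates smaller parcellations
proportionally by largest remainder.

## The cross-twin engine

Each of B bootstrap iterations (default B = 1000, matching the full
design; validation runs use B = 50) draws a fair coin per pair to decide
which member trains and which tests, so no subject ever appears in both
groups of one iteration — this is asserted structurally every iteration.
Within the training group:

1. **Screening.** Each edge is tested univariately against the adjusted
   G-score: F = r²(n−2)/(1−r²) on F(1, n−2); edges with p < 0.05 are
   kept. Screening is recomputed inside every iteration and every
   permutation, never on the full cohort, to avoid leakage.
2. **PLS regression.** Partial least squares with a single response
   (PLS1/NIPALS, predictors standardized, response centred). The
   component count is chosen by 5-fold cross-validation within the
   training group over a grid from 1 up to `max_components`, maximizing
   the mean held-out Pearson correlation; ties go to the fewest
   components. The grid cap is 100 by default (the full-scale grid) and
   is automatically clipped to the data rank; desk-scale validation runs
   cap it at 20 (about n_train/4 at 80 training subjects), which is
   where the grid becomes rank-limited noise at that sample size.
3. **Scoring.** The refit model predicts the co-twin group; performance
   is the Pearson correlation between predicted and observed G-scores.
   Zero-variance predictions score 0 by documented convention.

Both fold directions are run (train→test and test→train); the reported
per-iteration r is the first direction, and both directions' selected
edge sets are retained for the consensus analysis.

**Permutation null.** For each of the B models, the training G-scores
are shuffled `perms_per_model` times (default 100) and the *entire*
pipeline — screening included — is rerun, pooling B × perms draws. The
procedure is deliberately a full-pipeline null: permuting only the final
fit would inherit the screening's selection optimism. The p-value uses
the add-one convention p = (1 + #{null ≥ observed})/(1 + N), which can
never return zero and is valid (super-uniform) for any N.

The inner-CV criterion, the permutation target (training labels) and the
pooling scheme are choices the package fixes and logs in the result
object; alternatives (test-label shuffling, per-model nulls) would also
be defensible.

## G-score handling and twin statistics

Raw G-scores are residualized on age and gender by OLS
(`adjust_gscore()`); a single-level gender column is dropped with a
warning since cohorts of same-sex pairs subsetted by gender can be
degenerate. Twin-pair correlations offer two conventions: roster order
(first-listed member vs second) and double entry, which correlates the
doubled pairing {(a,b), (b,a)} and is exactly invariant to member order
— there is no natural within-pair ordering, so order-sensitive tests use
the double-entry variant. Falconer's h² is reported unclipped (with a
warning outside [0, 1]) because the estimator is unbounded and clipping
would hide sampling behaviour.

## Consensus edges, node strength, fingerprinting

An edge is *fold-consistent* in an iteration if selected in both LOGOCV
directions; its consensus count is the number of such iterations.
`threshold_consensus()` keeps edges whose count strictly exceeds a
fraction of B (default 0.5): at B = 1000 a count of 500 is excluded, 501
included — "more than half", taken literally, with the boundary
documented. Node connectivity strength sums retained edges incident to
the node (optionally weighted by |edge weight|); the handshake lemma
(strengths summing to twice the edge count) is enforced by test. Top-k
rankings break ties by ascending node id for determinism.

Fingerprinting correlates a probe subject's (optionally masked) edge
vector against every other individual in the same-zygosity cohort and
predicts the argmax; both members of every pair are probed, each attempt
counting once. Accuracy is the percentage of attempts that hit the true
co-twin; chance is 100/(n−1)% for n individuals.

## The difference models

`pair_differences()` forms, per pair, the scalar |G_a − G_b| and the
per-edge vector |x_a − x_b| — the "distance" here is coordinate-wise
absolute difference, since the per-edge differences are needed as
features, not collapsed into one norm. The k-fold engine (default
k = 10) ranks edges by the same univariate F statistic within training
folds only, keeps the top `top_m` (default 400; a network with fewer
intra-network edges contributes them all), fits the same PLS machinery
and predicts the held-out fold. Evaluation correlates the *pooled*
out-of-fold predictions with the observed differences — one r per
cohort, which matches how a single headline correlation per cohort is
conventionally reported; a per-fold-mean variant is exposed via
`per_fold_r`. Significance comes from rerunning the full CV on permuted
differences (default 5000 permutations at full scale).

## Comparing MZ and DZ accuracies

`compare_independent_correlations()` implements the Fisher z test,
z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)), with Cohen's
q = atanh r₁ − atanh r₂ and Zou's (2007) asymmetric confidence interval
for r₁ − r₂. Power uses the two-tailed normal approximation
Φ(z_eff − z_{α/2}) + Φ(−z_eff − z_{α/2}), which correctly returns α at
q = 0; the opposite-tail term is tiny at practical effect sizes.

One convention matters and is therefore an explicit argument, never
inferred: the *sample size*. Correlations computed across individuals
(the cross-twin mean-r contrast) are compared with per-individual counts
(e.g. 178 vs 100); correlations computed across pairs (the difference
models, one observation per pair) use per-pair counts (89 vs 50). Both
conventions are exercised in the test suite against worked examples.

## The synthetic cohort generator

Restricted family data cannot ship with a package, so validation runs on
cohorts drawn from an explicit generative model (`twin_sim_params()`,
`generate_cohort()`):

* per pair, a latent edge profile g_p ~ N(0, I); member i receives
  x_i = √ρ g_p + √(1−ρ) e_i, so each edge has unit variance and exact
  within-pair correlation ρ;
* G_i = β Σ_j w_j x_ij over k causal edges (w equal-magnitude,
  unit-norm) + s_p + σ ε_i, with s_p ~ N(0, c) a shared-pair
  environmental term;
* ages uniform on 22–36 shared within pair; genders Bernoulli(0.5) per
  pair (same-sex pairs); optional linear demographic effects that the
  adjustment step removes.

The implied co-twin G correlation is (β²ρ + c)/(β² + σ² + c)
(`analytic_twin_g_correlation()`), the oracle for parameter-recovery
tests. Defaults were fixed once: 89 pairs (the MZ cohort size of the
motivating design), R = 268 with R = 40 for desk-scale runs, ρ presets
0.8 (MZ) and 0.2 (DZ), k = 79 causal edges (mirroring the consensus-set
size the cross-twin analysis yields at full scale), β = 1, σ = 1, c = 0
— giving analytic twin-G correlations of 0.4 (MZ-like) vs 0.1 (DZ-like)
and h² ≈ 0.6, a qualitatively realistic contrast. Causal edges are drawn
uniformly unless `causal_network` plants them inside one network (used
by the planted-DMN validation).

What the generator does *not* emulate: spatial autocorrelation of real
parcellations, heavy-tailed and heteroscedastic FC noise, haemodynamic
autocorrelation (the optional time-series emitter draws i.i.d. Gaussian
samples from a target correlation matrix, projected to positive
definite by eigenvalue flooring — it exercises the ingestion path, not
BOLD physics), motion artefacts, and any environment–genotype
interaction. Passing validation therefore certifies the *machinery* —
no leakage, calibrated nulls, recoverable planted signal, correct
statistics — not performance on real twins.

## Validation problem sizes

The acceptance-style tests run: parameter recovery and ρ-monotonicity at
R = 40, 80 pairs, B = 50, 20 permutations per model (with the trend
averaged over three replicate cohorts per ρ to keep cohort-level noise
below the effect); null calibration on 50 replicate null cohorts
(30 pairs, R = 20) with a Kolmogorov–Smirnov uniformity check on both
engines' p-values; planted-DMN recovery over 20 replicates at R = 40;
fingerprint sanity at ρ ∈ {0, 0.1, 0.5, 0.9, 1}; and exact oracle
equivalence of the screening F statistics against explicit per-edge OLS.
These sizes are the package's chosen trade-off between Monte Carlo
resolution and a test suite that runs in minutes on one CPU.

## Numerical choices and degenerate inputs

* Fisher transform clamps |r| at 1 − 1e−12; symmetry tolerance for
  vectorization is 1e−10.
* Constant edge columns get F = 0 / p = 1 (never selected); constant
  predictors inside PLS are left centred with unit divisor; a response
  orthogonal to all predictors yields the mean model.
* PLS component extraction stops when residual covariance falls below
  1e−12; the grid cap is clipped to min(n − 1, p, smallest inner-fold
  training size − 1).
* Zero-variance predictions score r = 0 with a warning; zero-variance
  fingerprint candidates are excluded with a warning.
* All stochastic stages consume explicit integer seeds; bootstrap
  iteration b uses seed + b, so iterations are independently
  reproducible.

## Known limitations

PLS1 is the only built-in learner (the engine's surface would admit
other regressors, but none are implemented). The consensus rule assumes
exactly two folds per iteration, as LOGOCV provides. The power
calculation is asymptotic, slightly liberal at very small n. Falconer's
formula is a moment estimator that ignores shared environment beyond the
equal-environments assumption; the generator's `shared_env` parameter
exists precisely to let tests quantify that bias. Finally, conclusions
from synthetic validation transfer to real cohorts only to the extent
the generative model's assumptions (unit-variance independent edges,
sparse linear edge→G coupling) hold — which is why they are stated here
rather than buried in code.
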