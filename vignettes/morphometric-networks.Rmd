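---
title: "Modeling and testing morphometric connectivity networks with mregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and testing morphometric connectivity networks with mregnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mregnet)
```

## The problem

Atrophy measured by longitudinal volumetric MRI is a candidate biomarker for
neurodegenerative disease, but single-structure ("mass univariate") analyses
lack specificity: many disorders shrink the same individual structures. A
more specific signature is the *pattern* of co-atrophy — which structures
lose volume together. mregnet models that pattern per subject: each brain is
a graph whose nodes are anatomical structures and whose edges mark strong
absolute correlation between two structures' volume trajectories across
visits. Because every subject gets their own graph, between-subject
variability is modeled explicitly and group differences can be tested on a
well-posed generative model for graph-valued data.

## From volumes to graphs

`forward_fill_volumes()` turns a long-format volume table into a cohort:

* subjects need at least 3 visits (two points cannot define a meaningful
  trajectory correlation); subjects with fewer are dropped and counted;
* a missing volume at a later visit is replaced by the most recent earlier
  value for that subject and structure; a missing volume at the *first*
  visit cannot be filled, so such subjects are rejected with a diagnostic;
* disease groups come from the Clinical Dementia Rating: CDR ≤ 1 is
  none/mild (group 0), CDR > 1 severe (group 1).

`cohort_adjacency()` computes each subject's Pearson correlation matrix over
visits and thresholds it at |r| ≥ 0.8 (inclusive; the tie rule is fixed so
runs are reproducible). There is no gold standard for the threshold;
0.7–0.9 give similar results in our experience, and the value is exposed.
Correlations are computed on raw volumes over visit index — visit times are
kept only for the atrophy-rate baseline — and a flat (zero-variance)
trajectory, whose correlation is undefined, is mapped to 0 rather than a
non-number: a structure that never changes carries no co-atrophy signal.

## The generative model

For m subjects on n shared structures, the model has d unit-norm basis
vectors h_1, …, h_d (the *networks*, shared across subjects) and per-subject
loadings λ[s, k]. Edges are independent Bernoulli draws above the diagonal:

  A_s[i, j] ~ Bernoulli( sigmoid( Σ_k λ[s,k] h_k[i] h_k[j] ) ),  i > j,

mirrored below, with A_s[i, i] = 1 fixed. Two choices matter at this sample
size. First, the sigmoid link guarantees the edge-probability matrix lies in
[0, 1] for *any* finite parameters — a least-squares low-rank fit does not,
and at n ≈ 30–108 structures the violation is material. Second, the diagonal
is excluded from the likelihood: diagonal entries of a correlation matrix
are identically 1 and would otherwise distort the fit; with fewer than ~40
structures the distortion is large.

## Fitting

`fit_embedding()` minimizes the binary cross-entropy (BCE) loss — the
negative log-likelihood, averaged over subjects, summed over unordered pairs
— by plain gradient descent with separate fixed step sizes for the basis and
the loadings. The loading gradient scales like 1/m, which is why its step is
orders of magnitude larger. The default mode is greedy: dimension k is
optimized with dimensions 1..k−1 frozen, so networks come out ordered by the
variability they explain, like principal components. A joint mode optimizes
all dimensions simultaneously for comparison; on synthetic cohorts both
recover the same top-10 structures per network.

Numerical choices:

* **Initialization.** Each new basis vector starts at the leading
  eigenvector (largest |eigenvalue|) of the mean residual matrix
  mean_s(A_s − E_s), with the loading initialized to a small value carrying
  the eigenvalue's sign. This is the rank-one direction that reduces the
  residual fastest. We adopted it after observing that random initialization
  reliably trapped the second greedy dimension in a sign-mixed local optimum
  on desk-scale cohorts (fitted loss 274 vs 253 for the generating
  parameters); with spectral initialization the fit reaches or beats the
  generating loss and the edge-probability error drops fourfold. Exactly
  zero loadings are avoided because (h, λ=0) is a stationary point of the
  product parameterization.
* **Step sizes.** Defaults (2 for h, 20000 for λ) suit cohorts of several
  hundred subjects over ~100 structures. They are chosen as the largest
  steps that converge without oscillation; the same rule at desk scale
  (m = 50–200, n = 20–30) gives ~0.005 and ~200, which all examples and
  tests use. A divergence guard aborts with that advice when the loss grows
  past 10× its running minimum.
* **Stopping.** A fixed iteration budget per dimension (default 10000;
  1000–1500 suffices at desk scale) rather than a tolerance rule.
* **Gauge.** The model is invariant to (c·h_k, λ_k/c²) and to flipping the
  sign of any h_k. Basis columns are renormalized once per dimension, after
  its descent, with the scale absorbed into the loadings; signs are aligned
  (largest-|entry| positive) only for reporting. No constraint is placed on
  the sign of λ during optimization.
* **Dimension.** `select_dimension()` eigendecomposes each subject's
  correlation matrix and suggests the smallest k whose leading eigenvalue
  mass exceeds 80% for the median subject, with scree-plot data returned for
  an elbow reading.

## Testing group differences

All tests operate on the score tensor T[s,k,i,j] = λ[s,k] h_k[i] h_k[j] —
network k's pre-sigmoid contribution to subject s's (i, j) edge. Confounders
(age, intracranial volume, APOE copy count as a categorical variable) enter
through a design matrix D; the "two-groups" design D′ appends a binary
disease-status column. Each tensor entry is regressed on both designs, and
the test statistic is the SSE difference (combined minus two-groups — an
F-type numerator, nonnegative by nesting) summed down to the desired level:

* networks: X_k sums over subjects and both structure indices;
* network-structure pairs: X_{k,i} sums over subjects and the partner index;
* network-structure-structure triples: X_{k,i,j} sums over subjects only.

Diagonal (i = j) cells are excluded throughout, for the same reason they are
excluded from the likelihood; triples are reported on unordered pairs i < j
since the tensor is symmetric in (i, j). The familywise error rate is
controlled at 5% by max-statistic permutation: disease labels are shuffled
(confounder columns stay attached to their subjects), the maximum statistic
over the level's whole family is recorded each time, and the threshold is
the 95th percentile of those maxima. Corrected p-values use the add-one
convention (1 + #{perm max ≥ observed}) / (1 + n_perm), so they are never 0
and ties count conservatively against rejection. Setting
`confounders = FALSE` swaps D for an intercept-only design, in which case
fitted values are plain (group) means — the unadjusted analysis variant.

Two conventions were genuinely open and are fixed as follows: labels (not
residuals) are permuted under confounder adjustment — Freedman–Lane-style
residual permutation would be the natural alternative — and rejection is
decided by the percentile threshold, with p-values reported alongside (the
two rules can differ only at ties). Inside the permutation loop the
two-groups regression is computed through the added-variable identity
(adding one column z to D reduces each response's SSE by (z̃'y)²/(z̃'z̃)
with z̃ the residual of z on D), which is algebraically exact and verified
against the two-full-regressions route at 1e-10 in the test suite.

## Baselines

`mass_univariate_test()` is the traditional single-structure comparison on
atrophy rates — per-subject least-squares slope of volume on years, over
baseline volume (robust to uneven visit spacing) — with the same
max-statistic permutation machinery. `pairwise_correlation_test()` compares
per-subject correlation values pair by pair (combined-mean vs group-mean
SSE), optionally after a Fisher z-transform; `pair_overlap()` reports the
percentage of its rejected pairs also found among the triples test's
structure-structure marginals. `disease_classifier()` is a demonstration
endpoint, not a contribution: two logistic regressions (confounders only vs
confounders plus loadings) compared by out-of-fold ROC-AUC on identical
stratified splits.

## What the synthetic cohorts emulate

`simulate_graph_cohort()` draws covariates (age uniform 60–90; ICV normal
1.5e6 ± 1.5e5 mm³; APOE copies 0/1/2 with probabilities 0.6/0.3/0.1, near
population frequencies), assigns a severe fraction of 0.35 (matching a
typical none/mild vs severe split of a longitudinal dementia cohort), and
generates loadings as

  λ_s = λ_base + shift·group_s + linear confounder effects + noise,

then samples each subject's graph from the model. Defaults — m = 100,
n = 30, d = 2, λ_base = 25 per network, noise 3 — put within-network edge
probabilities near 0.85 and background near 0.5, comparable to thresholded
real correlation graphs, at a size where a fit takes seconds. Confounder
effects act per standard deviation of the covariate and linearly on λ,
mirroring the linear adjustment the testing module assumes, so the
adjustment path has a well-posed recovery target. The full truth (basis,
loadings, probabilities) is returned for calibration and recovery studies.
A planted shift of −18 on one network moves its block edge probabilities by
about 0.2 — the effect size used in the power checks.

`simulate_volume_cohort()` feeds the preprocessing path: blocks of
structures share one latent random-walk trajectory (step 5% of baseline
volume per visit) plus 0.5% independent noise, making within-block
trajectory correlations ≈ 0.99 in expectation; missingness is injected after
baseline at a configurable rate; six visits 6 months apart by default.

What these generators deliberately do **not** emulate: spatially structured
measurement error, scanner/site effects, informative dropout, nonlinear
atrophy trajectories, and disease heterogeneity beyond a single loading
shift. Passing calibration and power checks on these cohorts therefore
demonstrates the statistical machinery is correct under the model's own
assumptions — not that real cohorts satisfy those assumptions.

## Problem sizes used in the checks

The test suite and the calibration script run at desk scale, chosen so each
check exercises the full pipeline in seconds to a couple of minutes: FWER
calibration uses 200 null cohorts (m = 100, n = 30, d = 2) with 500
permutations each, statistics computed on the generating-truth tensor (the
test's calibration does not depend on refitting, and this isolates it from
optimization error); recovery fits use m ∈ {50, 200}; power uses 20
replicates of the planted one-network shift. Paper-scale runs (m ≈ 500,
n ≈ 108, d = 4, 10000 permutations) use the same code paths with larger
arguments.

## Known limitations

* Plain gradient descent with fixed steps requires scale-appropriate step
  sizes; there is no line search or adaptivity by design (the procedure is
  part of the method's definition).
* Greedy fitting is not guaranteed to reach the joint optimum; it trades a
  small likelihood gap for ordered, interpretable networks.
* Raw-label permutation under confounder adjustment is exact only when
  confounders and labels are independent; with strong confounder-label
  association a residual-permutation scheme would be preferable.
* The structures-only and structure-structure-only test variants are served
  by the baseline implementations of the standard methods, not by the
  tensor machinery.
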