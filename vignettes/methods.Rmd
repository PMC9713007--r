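---
title: "Methods: ridge partial-correlation connectomes, graph topology and permutation inference"
author: "rsConnectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ridge partial-correlation connectomes, graph topology and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`rsConnectome` implements a complete two-group resting-state connectome
analysis starting from region-of-interest (ROI) time series. The pipeline
is the one used in resting-state case-control studies of substance-use and
other neuropsychiatric disorders:

1. **Connectivity estimation.** Per subject, a Tikhonov (ridge)
   regularized partial-correlation matrix is computed from the ROI time
   series and Fisher r-to-z transformed.
2. **Graph topology.** Each connectome is thresholded at every sparsity on
   a grid, weighted graph attributes are computed at each threshold, and
   each attribute's curve is integrated (trapezoid) into a single AUC
   value per subject.
3. **Group inference.** Edge-level differences are tested with the
   network-based statistic (NBS); AUC features are tested with a
   max-statistic permutation GLM; significant global attributes are
   correlated with clinical scores by Pearson partial correlation with
   Bonferroni adjustment.
4. **Classification.** LASSO-selected AUC features feed a linear SVM whose
   performance is estimated by repeated stratified cross-validation and
   tested by label permutation.
5. **Synthetic cohorts.** A generator plants known partial-correlation
   differences in two-group cohorts so that every stage above can be
   validated against ground truth.

# Connectivity model

Let $X$ be the $T \times N$ matrix of ROI time series (timepoints by
nodes). Columns are standardized to zero mean and unit variance, so the
sample covariance $\hat\Sigma$ is a correlation matrix. The regularized
precision is

$$\Theta = (\hat\Sigma + \alpha I)^{-1},$$

and the partial correlation between nodes $i$ and $j$ is read off the
precision as $\rho_{ij} = -\Theta_{ij} / \sqrt{\Theta_{ii}\Theta_{jj}}$.
At $\alpha = 0$ this equals the classical partial correlation — the
correlation of the residuals of $i$ and $j$ after regressing both on all
remaining nodes — which the test suite verifies against exactly that
oracle to $10^{-8}$. The ridge term keeps the inversion stable when $T$
does not greatly exceed $N$ (196 timepoints against 246 nodes in the
whole-brain setting); shrinkage is monotone: the largest $|\rho_{ij}|$ is
non-increasing in $\alpha$.

**Choice of $\alpha$.** The ridge weight used by the original toolbox
pipeline is not published, so the package treats it as a free parameter
with default $\alpha = 0.1$ after unit-variance standardization: large
enough to stabilize a $246$-node inversion at $T \approx 200$, small
enough that well-conditioned problems are barely shrunk. Whether to
standardize before estimation is likewise exposed only through the data
you pass in; the package always standardizes, which makes $\alpha$
scale-free.

Fisher's transform $z = \operatorname{atanh}(\rho)$ is applied entrywise.
Estimates within $10^{-9}$ of $\pm 1$ are clipped to magnitude
$1 - 10^{-12}$; anything farther past $\pm 1$ is an upstream error and
fails loudly rather than being silently repaired.

# Graphs and topological attributes

A connectome is turned into an undirected weighted graph at sparsity $s$
by keeping the $\lfloor s\,N(N-1)/2 \rfloor$ strict-upper-triangle entries
with the largest **signed** z values as edges (weights = z, ties broken by
node order). Ranking signed rather than absolute values keeps the
strongest positive couplings, and all retained weights must be positive
because the weighted metrics below are defined for positive couplings; a
grid dense enough to pull in non-positive weights raises an error instead
of silently dropping edges — the correct response is a narrower grid. The
conventional grid is $[0.05, 0.40]$ in steps of $0.01$ (36 thresholds);
edge sets are nested across increasing $s$.

Weights are rescaled to a maximum of 1 before any metric, so all topology
metrics except network strength are invariant to a global rescaling of the
connectivity values. Edge length for shortest paths is $1/w$ (stronger
connections are closer). At each threshold the package computes:

* **Cp** — Onnela weighted clustering, geometric mean of triangle weights,
  averaged over nodes (nodes of degree $< 2$ contribute 0). The attribute
  name alone does not pin down a weighted variant; Onnela's is the common
  choice in weighted brain-graph work and reduces to binary clustering at
  unit weights (verified against a brute-force oracle).
* **Lp** — mean of the finite pairwise shortest-path distances.
* **Sp** — mean nodal strength on the *raw* weights (the only
  scale-dependent attribute).
* **E.glob** — mean of $1/d_{ij}$ over ordered pairs, unreachable pairs
  counting 0.
* **E.loc** — mean over nodes of the efficiency of the neighbor-induced
  subgraph.
* **Q** — Louvain modularity, best of 10 restarts under randomized vertex
  orders (Louvain is order-dependent); seeded.
* **sigma, omega** — small-worldness against reference nulls (below).

Nodal attributes are nodal efficiency (mean inverse distance to the other
nodes) and unnormalized betweenness centrality on $1/w$ lengths.

**Disconnected graphs.** At sparse thresholds graphs can fragment. Lp
averages finite distances only and efficiencies count unreachable pairs
as 0, which keeps every grid point computable; this is the standard
convention for brain-graph AUC pipelines.

# Reference networks and small-worldness

$\sigma = (C_p/\langle C_p^{rand}\rangle)\,/\,(L_p/\langle
L_p^{rand}\rangle)$ uses degree-preserving random references built by
Maslov–Sneppen double-edge swaps (10 attempted swaps per edge), with the
weight multiset reassigned by random permutation.

$\omega = \langle L_p^{rand}\rangle/L_p - C_p/\langle C_p^{latt}\rangle$
additionally needs lattice references: the package latticizes by
degree-preserving double-edge swaps accepted only when they strictly
reduce the total ring distance $\sum \min(|i-j|, N-|i-j|)$ of the edge
set (5 passes over the edges). A network is conventionally called small
world when $\sigma > 1$ and $\omega \in [-0.5, 0.5]$; $\omega < 0$ leans
lattice-like, $\omega > 0$ random. The test suite checks exactly this
regime behaviour on Watts–Strogatz, ring-lattice and Erdős–Rényi graphs.

On triangle-free graphs (possible at very sparse thresholds on small
node counts) the clustering ratios are 0/0 and $\sigma$, $\omega$ are
returned as `NaN` rather than silently substituted; choose the grid so
the sparsest threshold still supports triangles.

**Reference count.** The number of references used by the original
analysis is not published; the default is 20 per grid point (configurable
up to whatever compute allows). Sampling noise from finite references is
absorbed into the test tolerances.

Each attribute's curve over the grid is integrated by the trapezoidal
rule into the subject's AUC feature. With local efficiency excluded (the
default, matching the conventional $7 + 2N$ feature space — 499 features
at $N = 246$), the feature table has one row per global attribute and per
nodal attribute × ROI; a flag keeps E.loc when desired. The table is a
`SummarizedExperiment` (features × subjects) carrying phenotypes as
`colData`.

# Group inference

**NBS.** For every upper-triangle edge of the (unthresholded) Fisher-z
matrices a GLM with intercept, group indicator and optional nuisance
covariates is fit; the group-contrast t statistics form a symmetric map.
Edges with $t$ above the one-sided $p < 0.001$ critical value are kept,
and connected components are extracted; component size is counted in
edges. The familywise null is the distribution of the largest component
size under Freedman–Lane permutation: the nuisance-only reduced model is
fit once, its residuals are permuted and added back to the reduced fit,
and the full model is refit on the pseudo-responses. Each direction
(increases, decreases) is tested with its own one-sided threshold by
negating the contrast. Degenerate zero-residual-variance edges get $t=0$
and are flagged rather than producing infinities.

**Max-statistic GLM on AUC features.** The same GLM and permutation
scheme, but two-sided ($|t|$) and with the maximum statistic recorded
within each *family* per permutation. The default family structure makes
each global attribute its own singleton family and each nodal attribute
one family across all ROIs, reconciling separate permutation budgets for
global and nodal levels with familywise control across regions. The exact
family over which the original analysis took its maximum is ambiguous in
the source description; the default here is declared, not inferred, and
fully configurable.

**P-value convention.** Permutation p values are $+1$-corrected by
default, $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$, which can
never be zero and is exact under exchangeability; a `paperConvention`
flag switches to the raw count$/B$ convention used in many published
pipelines. At $B = 99$ the smallest achievable corrected p is $0.01$.

**Clinical association.** Pearson partial correlations between
significant AUC attributes and clinical scores, controlling nuisance
covariates by residualizing both sides on them; p from the t distribution
with $n - k - 2$ df; one Bonferroni correction over the full attribute ×
clinical-variable grid.

# Classification

LASSO (L1-penalized logistic regression over the glmnet path) selects
features; the penalty minimizes the cross-validated binomial deviance
averaged over 10 repeats of stratified 5-fold CV (`lambdaRule = "min"`;
the 1-SE rule is available but retains fewer features). The linear SVM
uses $C = 1$. Min–max scaling to $[0,1]$ is always learned on the
training folds and applied unchanged to the test fold, so test values may
fall outside $[0,1]$.

Two selection orders are provided. `selectionMode = "nested"` (the
default) redoes LASSO inside every training fold — the statistically
sound order with no selection leakage. `"paper"` selects once on the full
data before cross-validation, replicating the publication-style order;
the suite checks directionally that this leaks (paper-mode accuracy ≥
nested-mode accuracy on null features). Accuracy, sensitivity (patient
class), specificity and chance-corrected kappa are aggregated over all
repeats × folds (mean ± sd, in percent); the ROC area — the Mann–Whitney
concordance of pooled decision values — is computed per repeat and
reported mean ± sd. The label-permutation test relabels subjects, re-runs
one round of k-fold CV per permutation (reusing the real-label selection
in paper mode, re-selecting per fold in nested mode), and compares mean
accuracies one-tailed.

# Synthetic cohorts

The generator is first-class, tested code: it defines the conditions
under which the pipeline is validated.

* **Backbone.** A shared sparse precision matrix: random support at the
  configured density, off-diagonal magnitude 0.2 with random sign, unit
  diagonal.
* **Planted differences** are specified on the partial-correlation scale
  (what the pipeline estimates), as signed deltas on listed edges. The
  group-2 precision re-derives the planted off-diagonals so the implied
  partial-correlation differences are exact; both precisions are then
  diagonally loaded by the *same* $\tau I$ until positive definite, and
  the edits are recomputed from the loaded diagonal at each iteration.
  Loading both groups identically is what keeps every off-planted partial
  correlation bitwise identical between groups.
* **Temporal autocorrelation.** Subjects are stationary Gaussian AR(1)
  series: the first sample is drawn from $N(0, \Sigma)$ and subsequent
  samples follow $x_t = \phi x_{t-1} + e_t$ with innovation covariance
  $(1-\phi^2)\Sigma$, so the contemporaneous covariance equals the target
  $\Sigma = \Theta^{-1}$ exactly for any $\phi$ — no post-hoc scale
  correction is needed. Default $\phi = 0.3$, a typical residual
  autocorrelation for band-passed BOLD at TR = 2 s.
* **Phenotypes.** Gaussian nuisance covariates (age 34.4 ± 8.9 y,
  education 13.3 ± 4.0 y, nicotine-dependence score 6.0 ± 2.7) and
  clinical scores (anxiety 22.4 ± 8.6, psychiatric rating 39.1 ± 11.1)
  with means and spreads matching the two-group study design the package
  targets; each clinical score is `mean + beta * z(summary) + noise`,
  where the summary is the subject's mean ridge partial correlation over
  the planted edges. `beta = 0` by default (no built-in association);
  the source study gives no effect-size information for its real data,
  so nonzero values are calibration choices, not estimates.
* **Defaults** mirror the target design (46 + 46 subjects, 246 nodes, 196
  timepoints). The validation suite runs a desk-scale version — 20 + 20
  subjects, 60 nodes, 196 timepoints — that is structurally faithful
  while keeping hundreds of simulated cohorts affordable.

**What the generator does not emulate:** BOLD hemodynamics, scanner and
physiological noise, head motion, spatial structure of the parcellation,
or heavy-tailed/nonstationary dynamics. Passing calibration and recovery
tests on these cohorts shows the inferential machinery is correct and
well-calibrated under the stated generative model; it does not certify
effect sizes or power on real fMRI data.

# Numerical and design choices

* Retained-edge count uses `floor()` — deterministic, never exceeding the
  nominal sparsity.
* The edge-wise GLM is solved for all edges at once by matrix algebra
  (one Cholesky of $X^\top X$, then matrix products per permutation), so
  5000-permutation NBS runs are matrix-multiplication bound.
* All randomness descends from one integer seed through named substreams
  (`childSeed`), so changing, say, the NBS permutation stream cannot
  perturb the simulated cohort; identical configuration and seed
  reproduce byte-identical pipeline outputs.
* Single-class folds (possible at tiny n) cause the repeat's split to be
  redrawn, with a logged message.
* Component size is measured in edges (the NBS extent convention); node
  sets are reported alongside.
* Validation problem sizes: 200 null cohorts at 200 permutations for the
  FWE calibration bands, 50 planted cohorts for NBS recovery, 10 seeds
  for small-world regime checks. These sizes give binomial 95% bands of
  about ±3 percentage points around a nominal 5% rate, which is what the
  acceptance bands encode.

# Known limitations

* **NBS discreteness at small edge counts.** The largest-component-size
  statistic is integer-valued; at the desk-scale validation conditions
  (60 nodes, primary threshold p = 0.001, so under 2 expected
  suprathreshold edges per null dataset) its null distribution sits almost
  entirely on sizes 0–2, and the achievable familywise error at a nominal
  0.05 is about 1%. The procedure remains exactly valid (never
  anti-conservative) but is conservative at this scale; the calibration
  rate the suite and the acceptance script report should be read with
  that in mind. At whole-brain edge counts the statistic is far better
  resolved.

* Only ridge-regularized partial correlation is provided (no graphical
  lasso, no full-correlation connectomes) and only positive-weight graph
  metrics.
* Louvain restarts make Q reproducible but still a lower bound on the
  optimal modularity.
* The latticization objective is the ring distance in storage order; for
  graphs whose natural geometry is not a ring it is a generic lattice
  surrogate.
* The publication-style classifier order is provided for comparability; its
  optimism is a property of that order, not of this implementation.
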