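---
title: "Two-wave symptom networks: models, choices, and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-wave symptom networks: models, choices, and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`clpnet` implements the standard two-wave psychometric network workflow
for ordinal symptom inventories — here, the 17 items of the GAD-7
(anxiety, A1–A7), a 7-item CES-D (depression, D1–D7) and the 3-item
UCLA scale (loneliness, L1–L3), measured on the same participants at
two occasions.  This vignette explains the statistical models, the
tunable parameters and their defaults, the design choices that were
genuinely open, and what the bundled synthetic generator does and does
not emulate.

## The contemporaneous model

Within a wave, responses are modelled by a Gaussian graphical model
(GGM) after a *nonparanormal* transform.  Each ordinal column is mapped
to normal scores of its mid-ranks,

$$z_i = \Phi^{-1}\!\big(\mathrm{mid\text{-}rank}_i/(n+1)\big),$$

Winsorized at $\delta_n = 1/(4 n^{1/4}\sqrt{\pi \log n})$ and
standardized.  Mid-ranks keep the map well defined and symmetric under
the massive ties of 4-category items; the transform is monotone and
idempotent on ranks.

The precision matrix $K$ of the transformed scores is estimated by the
graphical lasso,

$$\hat K = \arg\max_K \; \log\det K - \mathrm{tr}(SK)
  - \lambda \sum_{i\neq j} |K_{ij}|,$$

with $S$ the correlation matrix and an unpenalized diagonal, solved by
block coordinate descent (compiled code; convergence `1e-4` on the
maximum coordinate change, at most 1000 sweeps).  Edges are the partial
correlations $w_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$.

**Penalty selection.** The rotation information criterion (RIC)
independently permutes the rows of every column — destroying all
cross-column dependence while preserving marginals — and records the
maximum absolute off-diagonal correlation of the rotated data.  The
selected penalty $\lambda^\*$ is the mean of those maxima over 20
rotations (the smallest value of the 100-point log-spaced path at or
above it is used).  The "mean of per-rotation maxima" aggregation is
one of several defensible readings of the criterion; it is recorded in
the network's metadata, and EBIC ($\gamma = 0.5$) is available through
`net_config(criterion = "ebic")` as an alternative.  RIC is
deliberately conservative: at the selected penalty a dependence-free
dataset produces (almost) no edges, which is what the null-recovery
tests verify.

## Communities

Non-overlapping communities come from the spinglass algorithm: the
signed Potts Hamiltonian (positive within-community weight rewarded
against a configuration null, negative weight penalized) is minimized
by simulated annealing via igraph, restarted `n_spins` times (default
500, following the published setting); the restart with the smallest
Hamiltonian wins, ties broken by the lexicographically smallest
canonical labeling so results are reproducible.  Components are
partitioned separately; components of one or two nodes are a community
by themselves, since annealing is undefined there.

Overlapping communities come from weighted clique percolation: all
$k$-cliques of the nonzero-edge graph are enumerated, those with
intensity (geometric mean of absolute edge weights) below $I$ are
dropped, and retained cliques sharing $k-1$ nodes chain into
communities.  Defaults $k = 4$, $I = 0.08$ follow the published
analysis.  Nodes in two or more communities are the *percolated*
(overlapping) symptoms.  Intensities use absolute weights — estimated
symptom networks here are almost entirely positive, and the original
treatment of negative edges is unstated; a signed variant would only
change cliques containing negative edges.  A numerical tolerance of
`1e-12` keeps cliques sitting exactly at the threshold (the geometric
mean is computed in the log domain).

## Centrality and predictability

One-step expected influence is the signed row sum
$EI1(i) = \sum_j w_{ij}$; two-step adds the edge-weighted one-step
values of the neighbours.  Bridge variants restrict the sums to edges
crossing community boundaries, computed against the spinglass partition
of the same wave.  Predictability is the $R^2$ of each node regressed
on its estimated neighbours, on the transformed scores — the
transformed-score OLS choice is documented in `predictability()`; the
nodewise mixed-model alternative was not adopted because the pipeline
operates entirely on Gaussianized scores.

## Comparing waves

`network_structure_test()` is a permutation test treating the two waves
as independent groups (as in the published analysis; with partially
overlapping participants this is an approximation, which we document
rather than repair).  Group labels of the pooled rows are permuted;
both networks are re-estimated *with the full pipeline including
penalty reselection* each time; the maximum absolute edge difference
M, the global-strength difference S, per-edge differences
(Holm-corrected across edges) and per-node EI1 differences
(Holm-corrected across nodes) are referenced to their permutation
distributions with the $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$
convention, so p-values are never exactly zero.  Both groups share one
rotation-seed per estimation round, making M and S exactly symmetric
under swapping the groups.

## The cross-lagged panel network

Each standardized wave-2 item is regressed on all standardized wave-1
items with a lasso penalty over 100 log-spaced values
($\lambda_{\min} = 10^{-4}\lambda_{\max}$; glmnet's early path
truncation is disabled so the full sequence is always available); the
penalty with the lowest 10-fold cross-validation error is selected, the
published rule.  Diagonal entries of the resulting $17 \times 17$
coefficient matrix are autoregressive paths.  In-prediction is the
squared correlation between a node's linear predictor and its observed
scores; out-prediction is the sum of squared outgoing standardized
coefficients *excluding* the autoregressive path (a node whose only
nonzero path is autoregressive has out-prediction 0, matching the
published convention of a non-autoregressive item having the minimum
out-prediction; `include_auto = TRUE` restores the inclusive sum).

Selection by minimum CV error is known to be liberal: at $n = 4000$ it
retains tens of spurious paths, all tiny ($|\beta| < 0.04$ in our
simulations), alongside every true path.  Users who need a sparse
support should refit or threshold; the package reports the selected
model as estimated.

**Fit indices.** The selected structure is refit without penalty as a
path model — T1 covariances saturated, T2 residuals uncorrelated — by
equation-wise least squares on the retained supports, which is the ML
solution of that model.  $\chi^2 = (n-1)F_{ML}$, CFI/TLI against the
independence baseline, $\mathrm{RMSEA} =
\sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}$, SRMR as the root mean squared
standardized residual (diagonal included).  When the baseline
chi-square does not exceed its degrees of freedom, CFI is 1 by
convention.  Note the model's diagonal-residual assumption: data whose
wave-2 innovations are correlated (as under the default generator,
which gives wave 2 its own within-wave network) will misfit even with a
saturated path structure; the fit-sanity checks therefore use a
generator variant with diagonal innovations.

## Stability

`edge_bootstrap()` re-estimates the network on row resamples (penalty
reselected each time — the interval reflects end-to-end uncertainty)
and reports percentile intervals.  These intervals are calibrated
around the *estimator*: with 4-category discretization attenuating
latent correlations and the lasso shrinking weights, an interval for a
latent generating weight of 0.25 concentrates near 0.15 — the tests
accordingly check coverage of the estimator's own population value.
`case_dropping_cs()` implements the field-standard CS-coefficient: the
largest drop proportion (grid 0.05–0.75) at which ≥95% of subsample
re-estimates correlate ≥0.7 with the full-sample statistic.

## The synthetic generator

`synthetic_config()` describes a latent Gaussian two-wave truth:

* **Structure.** 17 items in communities of 7/7/3.  Within each
  community the nonzero partial correlations form a ring at weight 0.25
  — an equal-weight sparse topology that stays positive definite
  (dense equal-weight blocks at 0.25 are indefinite); four bridge edges
  at 0.15 (A2–D1, A4–D1, D5–L1, D4–L2) echo the reported bridging
  symptoms.  The constructor verifies the smallest eigenvalue of the
  implied precision matrix and names it on failure.
* **Waves.** Latent T1 scores are multivariate normal with the implied
  correlation matrix.  Latent T2 is the cross-lagged linear map of T1
  (autoregressive 0.4 everywhere except A1, which the published
  temporal network found non-autoregressive; cross paths L3→A1 0.37,
  L2→A1 0.28, D6→L2 0.30) plus correlated innovations scaled so T2
  latent marginals have unit variance — configured coefficients are
  therefore standardized.
* **Ordinal measurement.** Four categories per item, thresholds
  $\Phi^{-1}(c/4) \pm s$ with skew shift $s = 0.8$: anxiety and
  loneliness items pile up in the lowest category, reverse-coded
  depression items in the highest, mimicking the heavy skew typical of
  these inventories in community samples.
* **Not emulated.** Real marginal distributions, missingness, partially
  overlapping wave samples (the generator pairs all participants; the
  published waves differ in size, implying an unstated matching step),
  item-specific loadings, and any model misspecification beyond
  discretization.  Passing recovery tests therefore show the pipeline
  is correct and well calibrated *under the latent-Gaussian-threshold
  model it assumes*, not that real panels satisfy that model.

## Problem sizes and numerical choices

The test suite runs recovery at $n = 2000$ (20 panels), comparison
calibration with 200 null replications × 200 permutations at $n = 500$
per group and 100 powered replications at $n = 1000$, cross-lagged
recovery at $n = 4000$ (20 panels), and stability at $n = 5000$ with 50
subsamples per drop proportion — sizes chosen so the full suite
completes on a single CPU in well under half an hour while keeping
Monte-Carlo error far from each decision boundary.  Degenerate inputs
are handled explicitly: zero-variance items are rejected at panel
construction; an empty network yields zero centralities and
predictabilities; undefined correlations (constant statistic vectors)
are reported as such and count as unstable in the CS analysis;
saturation penalties give the empty network exactly (the first path
value is pinned to $\lambda_{\max}$ against one-ulp drift).

## Known limitations

* The independent-groups comparison test applied to overlapping-sample
  waves inflates nothing under the null of equal structures but its
  power interpretation is approximate.
* RIC internals and the original spinglass annealing schedule are
  unstated in the source analysis; both are documented in metadata and
  results may differ from other implementations in ways that matter
  only near selection boundaries.
* Minimum-CV lasso retains small spurious cross-lagged paths by design;
  the sparsity of the printed temporal network should be read as "small
  paths are near zero", not "few paths are nonzero".
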