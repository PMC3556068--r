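---
title: "Piecewise-linear QSAR with an XCSF learning classifier system: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise-linear QSAR with an XCSF learning classifier system: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Quantitative structure–activity relationship (QSAR) models regress a
biological activity — here pIC50, the negative base-10 logarithm of the
half-maximal inhibitory concentration in molar — on numeric molecular
descriptors computed from compound structures. When a compound collection
contains several chemical series, the descriptor vectors concentrate in
separated regions of descriptor space (a multimodal distribution), and the
structure–activity relationship inside one series need not extrapolate to
another. A single global model, linear or not, then averages over
conflicting local trends. This package implements a *local* strategy: an
XCSF learning classifier system that evolves a small population of rules,
each pairing a region of descriptor space with its own linear model, and
compares it against global multiple linear regression (MLR) and a
feed-forward neural network (ANN) under a common cross-validation harness.

## The XCSF rule system

A rule (classifier) has three parts:

* **Condition** — an axis-parallel hyperellipsoid with center $m$ and
  strictly positive semi-axes $\sigma$ on the unit descriptor cube. It
  matches input $s$ iff $\sum_i ((s_i - m_i)/\sigma_i)^2 \le 1$.
* **Local linear model** — weights $w$ over the augmented input
  $(x_0, s)$; the rule's prediction is $w_0 x_0 + \sum_{i>0} w_i s_i$ with
  $x_0 = 1$ by default.
* **Bookkeeping** — prediction-error trace $\varepsilon$, fitness $F$,
  numerosity (copy count), experience, match-set-size estimate and a GA
  timestamp.

At each training step the *match set* of rules containing the current
input is formed; if fewer than $\theta_{mna}$ rules match (default 1), a
*covering* rule is created centered on the input with zero weights. The
system prediction is the fitness-weighted, numerosity-weighted average of
member predictions. Each member is then updated toward the observed
activity $P$:

* weights by recursive least squares (default) with gain
  $k = Va/(\lambda + a^\top V a)$ and covariance downdate
  $V \leftarrow (V - k (Va)^\top)/\lambda$, $V$ born as
  $\delta_{rls} I$ — or by the normalized delta rule
  $\Delta w = \eta (P - p) a / \lVert a \rVert^2$;
* the error trace by $\varepsilon \leftarrow \varepsilon +
  \beta(|P - p| - \varepsilon)$, averaged as a running mean while the
  rule's experience is below $1/\beta$ (MAM);
* fitness by the accuracy route: $\kappa = 1$ if
  $\varepsilon < \varepsilon_0$, else
  $\alpha (\varepsilon/\varepsilon_0)^{-\nu}$; relative accuracies
  $\kappa' = \kappa \cdot num / \sum \kappa \cdot num$ (which sum to 1 over
  the match set) drive $F \leftarrow F + \beta(\kappa' - F)$.

A niche genetic algorithm fires when the numerosity-weighted mean GA
timestamp of the match set lags the current step by more than
$\theta_{ga}$: two parents are drawn fitness-proportionately, uniform
crossover mixes their (center, stretch) allele vectors with probability
$p_c$, each allele mutates with probability $p_m$ by uniform
$\pm 0.1$ noise (the unit cube sets the allele scale; stretch is clamped
positive), and the two offspring inherit averaged parent weights, the
parental mean error, one tenth of the parental mean fitness, and a fresh
RLS covariance. Insertion is followed by roulette deletion — vote
proportional to match-set-size estimate times numerosity, inflated for
experienced low-fitness rules — until the micro-population is back at the
bound $N$ (default 30). Rules are maximally plastic where the GA needs
them and the bound keeps the model as small as a rule table should be.

Subsumption (absorbing a specialized rule into a more general accurate
one) is not implemented: containment testing between axis-parallel
ellipsoids has no clean closed form and the mechanism is not needed at
these population sizes.

### Prediction

`predict()` matches each query against the frozen population without
covering. A query outside every condition falls back to the nearest
condition by the same quadratic form, and the row is flagged
(`.fallback`); users should treat flagged predictions as extrapolations.

### Parameters that matter, and two calibration rules

All constants live in `xcsf_params()`. Two deserve emphasis because the
package's defaults encode lessons that generic XCSF defaults miss:

* **`eps0` (default 0.05 activity units)** — the error below which a rule
  counts as accurate. It must sit at or above the irreducible noise of the
  activity. If it is set below the noise floor, no converged rule can ever
  be "accurate", while a newborn rule — whose recursive least squares
  step nearly interpolates its first few samples, so its short MAM error
  trace is transiently tiny — scores $\kappa = 1$. Selection then inverts:
  the GA breeds newborns and deletion removes experienced rules, and the
  population churns without converging. We observed exactly this regime
  before raising the default to the noise scale of the synthetic
  benchmark (and of optimistic pIC50 assay repeatability); with noisier
  assay data `eps0` should be raised further (typical inter-laboratory
  pIC50 reproducibility is several tenths of a log unit).
* **`stretch_span` (default 2)** — covering draws each semi-axis uniformly
  from $(0.5r, 1.5r]$ where $r$ is the covering stretch. When a K-means
  model is supplied, $r$ is `stretch_span` times the mean point-to-center
  distance of the cluster nearest the covered input. The factor reflects
  geometry: the covered input is itself a cluster member sitting about one
  mean radius from the center, so spanning the cluster from there requires
  about twice the mean radius. With the factor at 1 a covering rule
  matches only ~10% of its own cluster, covering fires on most steps, and
  the bounded population again churns; at 2 the population stabilizes and
  test error reaches the noise floor.

Other defaults: $\beta = 0.2$, $\eta = 0.2$, $\theta_{mna} = 1$,
$\theta_{ga} = 50$, $\alpha = 0.1$, $\nu = 5$, $p_c = 0.8$, $p_m = 0.04$,
$\theta_{del} = 20$, $\delta_{del} = 0.1$, $\delta_{rls} = 1000$,
$\lambda = 1$, `cover_range` 0.17 (the no-cluster fallback on the unit
cube). The RLS covariance is re-symmetrized after each update; without
this, roundoff drift in $V$ limits agreement with the exact least-squares
solution to about $10^{-8}$ instead of $10^{-9}$.

The per-epoch training MSE in the model log is computed from the online
system predictions made while passing over the (shuffled) training data —
each prediction made before that step's updates — not from a second pass
with the frozen model. Early-epoch values therefore include covering-born
zero-weight predictions and overstate the error of the final model.

## Preprocessing pipeline

**Scaling.** Descriptors are min-max scaled to $[0,1]$ per *training*
fold; held-out rows are scaled with the training statistics and are
deliberately not clipped. Constant training columns map to 0.5 with a
warning. The unit cube makes `cover_range` and the mutation scale
meaningful.

**Descriptor reduction** follows the standard four-filter cascade, each
step reported in `selection_history()`:

1. near-constancy: drop descriptors whose modal value's frequency
   strictly exceeds 80%;
2. activity correlation: keep $|r(X_j, y)| \ge 0.7$ (absolute value — a
   strong negative correlate is informative; a flag restores signed
   thresholding);
3. cross-correlation: greedy scan in decreasing $|r(\cdot, y)|$ order
   (ties by column order), dropping any descriptor whose pairwise $|r|$
   with an already-kept one exceeds 0.7 — deterministic, and of a
   correlated pair the better activity-correlate survives;
4. bidirectional stepwise MLR on partial-F p-values
   (enter 0.05 / remove 0.10), with rank-deficient candidates skipped.

A final PCA step (correlation matrix, no rotation) retains components by
the Kaiser rule (eigenvalue > 1) or a fixed count and picks, per component
in eigenvalue order, the not-yet-chosen descriptor with the largest
absolute loading (ties by column order) — one representative per retained
component. These tie-break and variant choices are deliberate fixed
conventions where several equally standard options exist.

**Clustering.** K-means is run with k-means++ seeding, 10 restarts, and
farthest-point re-seeding of emptied clusters; $K$ is chosen by the mean
silhouette width over a scan (default 2–10, smallest $K$ on ties;
singletons contribute silhouette 0). The per-cluster mean point-to-center
distance is exported as the covering-stretch hint; a singleton cluster's
zero is replaced by the mean over non-singleton clusters.

## Baselines and comparison harness

MLR is ordinary least squares via QR. The ANN is a d–H–1 perceptron
(logistic hidden layer, linear output) fitted with `nnet`; an internal
15% validation split selects H from a grid (default 2–15) by validation
MSE, with a small weight decay (1e-3) as the regularizer — a deliberately
era-typical, deterministic-given-seed configuration rather than a modern
deep-learning stack. Whether such a validation split sits inside each
training fold or outside the cross-validation entirely is a protocol
choice; the harness keeps it inside the fold, which is the leakage-free
reading.

`cross_validate()` partitions compounds into k folds (sizes differing by
at most one; deterministic given the seed), and per fold: fits the scaler
on the training part only, fits every model specification on the scaled
training fold (for XCSF this includes the silhouette scan and K-means,
fold-internal), and records test-fold MSE, averaged over the
specification's repetition count (default 20 for the stochastic XCSF, 1
for deterministic MLR). Column means, sample standard deviations
(n − 1), and two-sided paired Student t-tests on the per-fold differences
(df = k − 1) summarize the comparison; pairs are marked significant iff
p < α strictly. Feature selection is applied before the harness by the
caller; running it once on all data (as historical studies often did)
leaks information, and the package's pipeline leaves it out of the fold
loop only if the user does.

## The synthetic benchmark generator

`generate_synthetic()` emulates the multimodal regime that motivates
local modelling: G Gaussian modes (default 4) on the unit cube in d
dimensions (default 7 — matching the size of a typical post-PCA
descriptor set), 150 compounds per mode with descriptor SD 0.05, and a
different affine activity surface per mode (slopes uniform in [−2, 2],
intercepts uniform in [4, 9] — a pIC50-like scale) plus Gaussian noise
(SD 0.05). Auto-generated centers are rejection-sampled to at least
4 descriptor-SDs of pairwise separation; samples are clipped to [0, 1],
a negligible distortion at these SDs. The generating labels and
coefficients are attached so tests can use per-cluster OLS as an oracle:
its residual MSE sits at the noise floor $\sigma_y^2$, while a global MLR
is several-fold worse (`global_vs_local_gap()` quantifies the gap).

What the generator does *not* emulate: realistic descriptor covariance,
heavy-tailed or correlated assay noise, cluster-dependent sample sizes,
activity cliffs, or any actual chemistry. Benchmarks passing on this
generator therefore demonstrate that the engine recovers piecewise-linear
structure under clean multimodality — not that it will match any
particular published error level on real compound data.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run, among smaller unit checks:
a 20-seed benchmark on the default generator (600 compounds, 75/25
split, silhouette scan 2–8, 50 epochs, population 30, RLS) comparing
XCSF's test MSE to global MLR's; a 60-run silhouette-recovery experiment
(G ∈ {2,3,4}, 20 seeds each, 40 compounds per cluster, center separation
0.4); and an equivalence check of a single always-matching RLS rule
against the exact least-squares solution on a 200 × 7 random design.
These sizes were chosen as the smallest at which the distinguishing
phenomena (noise-floor convergence, mode recovery) are stable across
seeds.

## Known limitations

* The rule population is bounded at 30 micro-classifiers by default;
  data with many more modes than that needs a larger `pop_limit`.
* Covering geometry assumes the unit cube; feeding unscaled descriptors
  silently degrades matching (use `normalize_descriptors()`).
* Out-of-coverage predictions are nearest-rule extrapolations and are
  flagged rather than suppressed.
* The published per-fold error table packaged for the summary/significance
  replica carries 4-decimal values; statistics computed from it can differ
  from their originally printed counterparts in the last digit (the
  packaged XCSF column's standard deviation recomputes to 0.0161 against
  a printed 0.0163).
* `stepwise_mlr()` refits via `lm` at each candidate step; for thousands
  of descriptors a screening filter first (steps 1–3) is assumed, as in
  the cascade's intended order.
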