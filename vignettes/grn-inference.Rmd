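---
title: "Inferring and evaluating gene regulatory networks with grnlasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and evaluating gene regulatory networks with grnlasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnlasso)
```

## The statistical model

grnlasso treats a panel of `p` genes measured on `n` samples as draws from
a multivariate Gaussian with covariance $\Sigma$. The object of interest is
the precision matrix $\Theta = \Sigma^{-1}$: $\Theta_{ij} = 0$ exactly when
genes $i$ and $j$ are conditionally independent given all the others, so
the off-diagonal support of $\Theta$ is an undirected gene network in which
an edge is a direct (partial) association rather than a mere marginal
correlation. Because small-sample estimates of $\Sigma^{-1}$ are dense and
unstable (and do not exist when $n < p$), $\Theta$ is estimated by
maximising the penalised log-likelihood

$$\log\det\Theta \;-\; \mathrm{trace}(S\,\Theta)\;-\;\lambda\,\lVert\Theta\rVert_1 ,$$

a convex problem whose $\ell_1$ penalty drives entries to exact zero. The
penalty here covers **all** entries of $\Theta$, diagonal included, and the
working covariance is initialised at $S + \lambda I$ with fixed diagonal —
one of two conventions in circulation (the other leaves the diagonal
unpenalised; `glasso_fit(penalize_diagonal = FALSE)` provides it, and the
test suite uses it to cross-check against an independent implementation
that adopts that convention).

## The solver

`glasso_fit()` implements the block coordinate descent:

1. Initialise $W = S + \lambda I$; the diagonal of $W$ never changes.
2. Cycle through columns. For target column $j$, partition $W$ and $S$ so
   that column $j$ is last ($W_{11}, w_{12}, w_{22}$; $s_{12}, s_{22}$); the
   stationarity condition for $w_{12}$ is the gradient equation of a lasso
   regression, solved by cyclic coordinate soft-thresholding
   (`lasso_cd()`), warm-started from the previous cycle; write back
   $w_{12} = W_{11}\beta$.
3. After convergence, recover $\theta_{22} = 1/(w_{22} - w_{12}^\top\beta)$
   and $\theta_{12} = -\beta\,\theta_{22}$ per column, symmetrise by
   averaging.

Numerical choices, all adjustable through arguments:

* **Outer convergence** (`tol`, default `1e-4`): stop when the mean
  absolute change of the off-diagonal of $W$ over one full cycle drops
  below `tol * mean(|off-diagonal of S|)` — the criterion of the
  coordinate-descent literature; the quantity is relative so that rescaling
  the data does not change the iteration count. A diagonal $S$ (no signal
  at all) falls back to an absolute threshold. `max_outer` (100) caps the
  cycles; a capped run returns a usable fit flagged `converged = FALSE`
  rather than failing.
* **Inner convergence**: the lasso runs at `tol/100` and additionally
  requires the subgradient residual to be within ten times its tolerance,
  so returned coefficients are genuine stationary points, not merely
  stalled iterates.
* **Sparsity** (`zero_eps`, default `1e-8`): soft-thresholding produces
  exact zeros and the recovery propagates them; `zero_eps` only mops up
  round-off introduced by the final symmetrisation. An edge is reported
  when `|theta_ij| > zero_eps`.
* **Warm starts**: `glasso_path()` fits a $\lambda$ grid in decreasing
  order, each fit started from the previous. This affects speed only; the
  tests verify path fits match cold fits.
* **Covariance** (`empirical_covariance()`): maximum-likelihood denominator
  `n`, matching the likelihood above; `standardize = TRUE` by default so
  the glasso runs on the correlation matrix — gene expression scales are
  heterogeneous and an unstandardised penalty would punish high-variance
  genes more. Both are explicit arguments because conventions differ
  between published analyses.

For $\lambda \ge \max_{i\neq j}|s_{ij}|$ every subproblem soft-thresholds
to zero and the network is empty; at $\lambda = 0$ the fit reproduces
$S^{-1}$. Both limits are tested.

## Evaluation against a gold standard

Curated interaction databases export directed, signed interactions;
`to_undirected()` collapses them (direction, sign, multiplicity and
self-loops dropped) because a precision-matrix support is inherently
undirected. `compare_networks()` counts edges as unordered label pairs over
the union of node sets — the gold standard and estimate need not list the
same nodes — and reports TP/FP/FN with precision, recall and f-score.
Zero-denominator cases (empty estimate or empty gold standard) score 0 so
that sweep tables stay total. `fscore_between()` is the symmetric form
$2|A\cap B|/(|A|+|B|)$ used to compare two estimates.

## The random-network null

An f-score of 0.4 between a 28-edge gold standard and a 27-edge estimate
means little without a reference. The null model: draw two edge sets
uniformly at random with the same sizes on the same `v` nodes, compute
their f-score, repeat (10,000 pairs by default); the p-value is the
fraction of pairs whose f-score **strictly exceeds** the observed one.
Under this null the overlap $C$ of the two edge sets is hypergeometric with
population $\binom{v}{2}$, so `exact_overlap_pvalue()` gives the exact tail
and the Monte-Carlo and exact routes cross-check each other in the tests.

Two deliberate conventions:

* **Strict inequality**, following the usual "more extreme than observed"
  reading. Attainable f-scores form a lattice $2c/(a+b)$ and the observed
  value typically lies on it, so counting ties would change p-values
  materially.
* **Unrounded observed f-scores.** Pass `f_obs` as computed (e.g.
  `2*12/(27+30)` = 0.42105…), never as the two-decimal value a table
  displays. A rounded-down threshold (0.42) silently shifts the exceedance
  cut from 13 to 12 common edges and nearly quadruples the tail (0.0100 vs
  0.0026 for 27- and 30-edge networks on 16 nodes). The package computes
  f-scores internally at full precision throughout; the display rounding
  in `write_report()` is cosmetic.

## Preprocessing and fold-changes

Microarray intensities are log2-transformed (`log2_transform()`, linear
scale enforced, strictly positive values) and quantile-normalized across
samples (`quantile_normalize()`, delegating to limma's implementation with
tie-averaging: tied values receive the mean of the reference distribution
at their tied ranks). Quantile normalization equalises column means exactly
and preserves within-column ranks; it is idempotent on tie-free data —
with ties the columns cannot share one distribution exactly, so exact
idempotence is guaranteed only for continuous data, which is what the
property tests use. The single-gene degenerate case returns the row mean
in every cell.

Fold-changes (`compute_fold_changes()`) are ratios of per-gene
linear-scale means (after/before) — one value per gene from grouped
samples, the common microarray convention — rather than means of per-pair
ratios; the two differ under noise and the choice is documented, not
inferred. A fold-change of exactly 1 is classed induced (closed boundary,
arbitrary). `summarize_fold_changes()` averages within the induced
(`>= 1`) and repressed (`< 1`) groups; `radiation_foldchanges()` bundles a
published 21-gene example whose group means (3.02 and 0.53 in one dataset,
3.12 in the other) the tests reproduce. Missing values are not supported
anywhere in the expression path: an NA is an error, never silently
dropped.

## The synthetic-data generator

Real irradiation studies of this kind have `p ≈ 16` genes, `n ≈ 8–15`
post-irradiation samples, and a gold-standard network of ~28 interactions
dominated by one hub of degree ~12 (MYC). The generator mirrors that
structure:

* `make_topology(p, m, hub_degree)` draws an `m`-edge graph uniformly;
  with a hub constraint, the hub's incident edges are drawn first (exactly
  `hub_degree` of them), the rest uniformly among non-hub pairs.
  `synthetic_radiation_network()` is a fixed-seed 16-node/28-edge/hub-12
  instance carrying real radio-responsive gene symbols — labels and shape
  only; the edge list is synthetic and claims no curated interaction.
* `topology_to_precision(g, rho, delta)` puts $\pm\rho$ on edge positions
  (random signs) and makes the diagonal the absolute row sum plus
  $\delta$: strict diagonal dominance guarantees positive definiteness
  with smallest eigenvalue at least $\delta$ *and* a support that equals
  the topology exactly, which eigenvalue-shifting constructions do not.
  Defaults $\rho = 0.3$, $\delta = 0.6$ give moderate partial correlations
  of the size seen in small expression panels; the recovery tests use
  $\rho = 0.4$.
* `sample_expression()` draws zero-mean Gaussians with covariance
  $\Theta^{-1}$ (the mean never enters covariance-based inference, so zero
  is the simplest sufficient choice) and tags them log2-scale.
* `make_paired_study()` builds positive linear-scale before/after matrices
  with per-gene fold-changes and multiplicative log-normal noise
  (`noise_sd` on the natural-log scale; 0.1 default ≈ 10% intensity
  noise), baseline levels log-uniform over a typical intensity range
  (2⁶–2¹²).

What the generator does **not** emulate: probe-level artifacts, batch
effects, heavy-tailed or count-like noise, dependent samples. Passing
tests therefore demonstrate correctness of the estimation and evaluation
machinery under the Gaussian model, not robustness to everything real
microarrays do.

## Problem sizes used in the tests

Fixtures are sized to what the methods actually face in this application:
16 genes or fewer, sample sizes from 15 (study scale) to 2000 (recovery
checks), 10,000-rep null simulations, 20,000–50,000-draw uniformity
checks, and a 50-instance cross-validation of edge sets against an
independent graphical-lasso implementation at `p = 10, n = 40`. The
structure-recovery benchmark (8 genes, 8 edges, $\rho = 0.4$, `n = 2000`,
ten seeds) asks for a best-over-grid f-score of at least 0.9 on average —
with that much data the support should be essentially recoverable, and it
is.

## Known limitations

* No $\lambda$ selection (BIC/AIC/stability) is provided; the package
  deliberately reports whole sweeps with per-row significance instead.
* The Gaussian assumption is taken at face value; no nonparanormal or
  rank-based robustification.
* The null model fixes only node and edge counts. Degree-preserving nulls
  would be stricter for hub-dominated networks and are out of scope.
* p-values along a sweep are not corrected for multiple testing across the
  grid rows.
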