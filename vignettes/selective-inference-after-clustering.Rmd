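---
title: "Selective inference for feature means after clustering: models, truncation sets, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective inference for feature means after clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postclust)
```

## The model and why conditioning is needed

We observe a data matrix $x \in \mathbb{R}^{n\times q}$ and model its rows
as independent draws $X_i \sim N_q(\mu_i, \Sigma)$ with unknown means and a
known positive-definite feature covariance $\Sigma$. After a clustering
algorithm $\mathcal{C}$ partitions the rows, we wish to test, for a pair of
estimated clusters $\hat G, \hat G'$ and a feature $j$,

$$H_0^j:\ \bar\mu_{\hat G j} = \bar\mu_{\hat G' j},$$

where $\bar\mu_{Gj}$ is the average of $\mu_{ij}$ over $i \in G$. The
statistic is $[x^\top\hat\nu]_j$ with contrast
$\hat\nu_i = 1\{i\in\hat G\}/|\hat G| - 1\{i\in\hat G'\}/|\hat G'|$, and its
null standard deviation is $\sqrt{\Sigma_{jj}\,\lVert\hat\nu\rVert^2}$.
Treating $\hat G, \hat G'$ as fixed and applying the two-sample Z-test is
anti-conservative, because the hypothesis was chosen by looking at the same
data: clustering algorithms produce visibly separated groups even from a
homogeneous population. The fix is to compute the p-value *conditional on
the clustering event* (and, for tractability, on the component $U(x)$ of
the data orthogonal to the statistic, which is independent of it under the
model). Rejecting when this selective p-value is below $\alpha$ controls
the probability of a false rejection *given that the hypothesis was
selected* — the selective type I error rate — in finite samples.

## The perturbation line and the truncation set

Conditioning on $U(X) = U(x)$ collapses the randomness to the scalar
statistic: the data compatible with the conditioning event form a
one-parameter family

$$x'(\phi, j) = x + \Big(\phi - (\bar x_{\hat G j}-\bar x_{\hat G' j})\Big)
  \frac{\hat\nu}{\lVert\hat\nu\rVert^2}\,
  \Big(\frac{\Sigma_j}{\Sigma_{jj}}\Big)^{\!\top},$$

which slides the tested mean difference to $\phi$ while co-moving every
correlated feature with slope $\Sigma_{jj'}/\Sigma_{jj}$ (`perturb_data()`;
the slope is verified to machine precision in the tests). The selective
p-value is then a two-sided tail probability of a
$N(0, \Sigma_{jj}\lVert\hat\nu\rVert^2)$ variable truncated to

$$\hat S_j = \{\phi : \mathcal{C}(x'(\phi,j)) = \mathcal{C}(x)\}.$$

Everything therefore hinges on computing $\hat S_j$ exactly.

### Hierarchical clustering

`hclust_trace()` runs bottom-up clustering on **squared** Euclidean
distances with Lance–Williams updates (single, average, centroid, Ward),
cutting after $n-K$ merges. The key geometric fact, which we derive and
exploit directly: along the perturbation line, rows of $\hat G$ all move by
the same vector, rows of $\hat G'$ by a common opposite vector, and other
rows do not move. Hence **every dissimilarity within a cluster of the final
cut is constant in $\phi$**, and so is every linkage value between
sub-clusters of the same final cluster. The $K$-cluster partition is
preserved if and only if, at each of the first $n-K$ merge steps, the
original winning merge — whose linkage value is the constant recorded
height — still attains the minimal linkage among the cluster pairs alive at
that step. Each comparison is a quadratic inequality in $\phi$, because
squared distances between perturbed rows are quadratics and the
Lance–Williams recursions for average, centroid and Ward linkage are linear
in the dissimilarities (coefficient triples are propagated through the
recursion). Three reductions keep the count at $O(n^2)$:

* one inequality per *co-alive cluster pair* suffices, with threshold equal
  to the largest winner height over the steps the pair is alive (window
  maxima are precomputed; centroid linkage may invert heights, so a running
  maximum — not the last height — is required);
* pairs whose linkage never varies in $\phi$ (e.g. both clusters outside
  $\hat G \cup \hat G'$) are satisfied at the observed data and for every
  $\phi$, and are dropped;
* single linkage, whose update involves a minimum rather than a linear
  combination, collapses to one inequality per *point pair* straddling two
  final clusters: its squared distance must stay at least the largest of
  the first $n-K$ merge heights.

### k-means

For Lloyd's algorithm the final-partition event can be reached through
exponentially many intermediate assignment histories, so the conditioning
event fixes *all* intermediate assignments $c_i^{(t)}$, $t = 0..T$
(`kmeans_trace()` records them). Both perturbed rows and perturbed
centroids — initial rows at $t=0$, cluster means of the previous assignment
afterwards — are affine in $\phi$, so each event "observation $i$ stays
nearest its assigned centroid rather than centroid $k$" is one quadratic
inequality; there are $n(T{+}1)(K{-}1)$ of them. Initialisation is plain
random-index sampling under a recorded seed: the conditioning event must be
a deterministic function of $(x, \text{seed})$, and the perturbed re-run
moves its initial centroids through the *same rows*. A k-means++-style
data-dependent initialisation would inject additional data-dependent
randomness into the conditioning event and is deliberately not offered.
Perturbations that would empty a cluster are excluded automatically, since
such assignment patterns differ from the trace.

### Interval algebra and tolerances

Solution sets of the quadratic inequalities are intersected as interval
unions (`intervals_intersect()`: complement of the union of complements,
one $O(N\log N)$ sweep). Numerical conventions, chosen once:

* a coefficient is treated as zero when its magnitude is below
  $10^{-10}\max(|a|,|b|,|c|,1)$ — distance-difference quadratics cancel
  their leading terms exactly in theory but not in floating point;
* intervals are closed (conditioning events are closed by continuity of
  the clustering criteria; the boundary is measure-zero and irrelevant to
  p-values); adjacent intervals with gaps below $10^{-9}\cdot s$ are
  merged and membership uses tolerance $10^{-8}\cdot s$, with scale
  $s = 1 + |\phi_{obs}|$;
* ties in linkage values or centroid distances are broken
  lexicographically (hierarchical) or by smallest cluster label (k-means),
  identically in the clustering, the truncation-set computation, and the
  brute-force oracles, so that re-clustering is a deterministic function.

The implementation's correctness contract is *oracle equivalence*: on a
401-point grid of $\phi$ values, membership in the computed $\hat S_j$ must
coincide with brute-force re-clustering of $x'(\phi,j)$ (comparing cut
partitions for hierarchical clustering, full assignment histories for
k-means) except within root tolerance of interval boundaries. The test
suite enforces this over 20 random data sets ($n \le 30$, $q \le 5$), all
four linkages and k-means with $K \in \{2,3\}$ — over 40,000 grid
comparisons with zero mismatches — and verifies $\phi_{obs} \in \hat S_j$
in every run.

### Truncated-Gaussian evaluation

Truncation sets routinely sit tens of standard deviations from zero — the
clustering was selected *because* the statistic is extreme. Each
interval's mass is computed from `pnorm(..., log.p = TRUE)` on the side
nearer the mean and combined by log-sum-exp; the selective p-value is a
ratio of such log-masses. A support 40 standard deviations out has mass
$\sim e^{-800}$: representable in log space, hopeless as a naive
difference of CDFs. Degeneracy (a support with *no* representable mass,
e.g. a zero-width interval) raises an error rather than returning 0/0,
because the observed statistic always lies in its own truncation set — a
violation indicates an upstream bug, not an unlucky data set. With an
untruncated support the selective p-value equals the classical two-sided
Z-test p-value to $10^{-12}$, a reduction identity the tests check
directly.

## What the simulations emulate — and what they do not

`simulate_design()` draws rows from $N_q(\mu_i, \Sigma)$ with
equicorrelated $\Sigma_{ij} = 1\{i=j\} + \rho\,1\{i\neq j\}$ and three mean
patterns: `fig1`/`null3` (50 rows elevated in feature 1, the remaining 100
in feature $q$, so features $2..q{-}1$ are global nulls for *any* pair of
estimated clusters) and `power3` (three groups of 50 at $-\delta/0/+\delta$
on the last $\lceil q/2\rceil$ features). `type1_experiment()` clusters
each replicate into $K=3$ groups, tests a random cluster pair on a random
null feature, and records naive and selective p-values;
`power_experiment()` uses the `power3` design and reports *detection
probability* (how often both tested clusters coincide exactly with true
groups) and *conditional power* (rejection rate among those replicates,
zero by convention when none detect). Two protocol details:

* selection randomness (pair, feature, k-means seeds) comes from a stream
  seeded independently of the data stream, so either can be varied alone;
* the power experiment draws the tested feature from the signal-bearing
  half only. Conditional power is meant to measure the test's ability to
  reject a *false* null; drawing from all features would cap it at roughly
  $\tfrac12 + \alpha/2$ and turn the $\delta$-response into a
  noise-dominated plateau. The monotonicity of power in $\delta$ is
  checked at $\rho = 0$, where detection probabilities (11–100% across
  methods at $\delta = 3$) keep the conditional estimand well-populated;
  at $\rho = 0.8$ several methods detect in under 4% of replicates at
  $\delta = 3$ and the conditional rate is not meaningfully estimable.

These generators emulate the distributional assumptions of the theory
exactly: independent Gaussian rows, known covariance, correctly specified
equicorrelation. Passing tests therefore demonstrate the *selective
machinery* is correct, not that the assumptions hold in real data. In
particular: scRNA-seq counts are not Gaussian (log-normalisation helps but
does not remove mean–variance coupling); the covariance there must be
estimated (`estimate_sigma()`, sample or within-cluster residual mode with
denominator $n - K$ and a ridge lift to positive definiteness), after which
error control is plug-in approximate rather than exact; and real data
violate row independence through batch effects. The preprocessing helpers
(`preprocess_matrix()`: QC filtering, per-cell total-count normalisation to
a configurable scale defaulting to the median cell total, $\log_2(x{+}1)$,
top-variance gene selection) implement the standard conventions but have
deliberately no default thresholds — the analyst must choose them.

## Problem sizes and reproducibility

The validation experiments in the test suite use $n = 150$, $q = 10$,
$K = 3$, with $M = 500$ replicates per correlation level for the type-I
study ($\rho \in \{0, 0.4, 0.8\}$, all four clustering methods) and
$M = 300$ per cell for the power study ($\delta \in \{3,5,8\}$); these
sizes give binomial standard errors below 0.01 on rejection rates while
keeping a full run in minutes on a single core. All experiments are exactly
reproducible from their integer seeds. Every hierarchical truncation set at
$n = 150$ intersects roughly $10^4$ quadratic inequalities and takes a few
tens of milliseconds; k-means sets are smaller still.

## Known limitations

* Known-$\Sigma$ exactness: with plug-in $\hat\Sigma$ the p-values are
  approximate; no finite-sample correction is attempted (none is known).
* Complete linkage and correlation-based dissimilarities are not supported:
  the quadratic characterisation of perturbed linkage values does not
  cover them.
* Conditioning for k-means fixes the entire Lloyd trajectory, which is
  stricter than conditioning on the final partition; the resulting test is
  valid but can be conservative relative to the (intractable)
  final-partition-only test. The tests verify the inclusion directly.
* Testing several features or several pairs multiplies dependent tests;
  the package applies BH across the returned rows, which is the field's
  convention, without a formal FDR guarantee under this dependence.
* Multi-feature contrasts (testing a gene set jointly) and selective
  confidence intervals are out of scope.
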