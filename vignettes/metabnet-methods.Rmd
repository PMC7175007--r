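---
title: "metabnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metabnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

`metabnet` analyses regional ¹⁴C-2-deoxyglucose (2-DG) uptake-ratio tables
— one dimensionless number per animal per brain region of interest (RoI),
the regional isotope concentration divided by the whole-brain concentration
of the same animal — for a two-genotype (WT, HET) by three-treatment
(saline, ketamine, d-amphetamine) cohort. Functional connectivity between
two regions is the Pearson correlation of their uptake ratios across the
animals of one experimental group. Thresholding the group correlation
matrix at a grid of values T gives a stack of binary undirected graphs on
which global architecture (mean degree ⟨k⟩, average shortest path length
L_p, mean clustering C_p) and regional centrality (degree k_i, betweenness
B_c, eigenvector E_c) are computed. Hubs are regions whose centrality
z-score against density-matched Erdős–Rényi graphs exceeds 1.96; group
differences are assessed by label permutation; rich-club cores by the
normalised rich-club coefficient; and seed-region connectivity by partial
least squares regression (PLSR), where a target region is a significant
functional connection of the seed when the lower bound of the jackknife 95%
CI of its VIP statistic exceeds 1.0.

## Network construction

* Correlations are Pearson, within group, across animals (≥ 3 animals
  required; zero-variance regions are an error). Fisher z = atanh(r) is
  stored alongside for reporting; thresholding operates on r, which induces
  the same ordering.
* Thresholding is **signed** and boundary-inclusive: an edge exists iff
  r ≥ T. A negative correlation never creates an edge under a positive
  threshold. `absolute = TRUE` switches to |r| if wanted; it is off by
  default because the thresholding rule is stated for the signed
  coefficient.
* The grid starts at `t_min` (default 0.49, step 0.01) and extends to the
  largest threshold at which **every** group's network is one connected
  component, capped at 0.95. With 59 regions there are 59·58/2 = 1711
  region pairs.
* On synthetic cohorts at the generator's default effect sizes the
  empirical networks are often disconnected at T = 0.49 — with ~10 animals
  the sampling SD of r around a baseline of 0.2 is roughly 0.3, so single
  regions can fail to reach 0.49 against every other region. Synthetic
  runs therefore pass a lower `t_min` (0.35, stepping down if needed),
  which is an analysis-configuration choice; real 2-DG data, with much
  stronger inter-regional coupling, supports the published 0.49–0.59
  window.

## Graph metrics

* L_p is the mean geodesic length over all unordered node pairs
  (breadth-first search in compiled code); disconnected graphs are an
  error by design — the grid construction guarantees connectivity for
  every analysed network.
* C_i is the triangle fraction among a node's neighbour pairs; nodes of
  degree < 2 contribute C_i = 0 to C_p by default (configurable to
  `exclude`). This keeps C_p defined on sparse graphs.
* B_c uses Brandes' accumulation with fractional credit for tied
  geodesics and is left unnormalised: all comparisons are within a fixed
  node count, where normalisation cancels.
* E_c is the entrywise non-negative principal eigenvector of the
  adjacency, scaled to max 1 (ties broken by lowest region index). The
  power iteration runs on A + I: on a connected graph A + I is primitive,
  so the iteration converges even for bipartite graphs, where A itself has
  a matching negative eigenvalue and plain power iteration oscillates. The
  shift leaves eigenvectors unchanged.
* Test oracles are fully independent implementations: geodesics and path
  counts from powers of the adjacency matrix, betweenness from the
  σ_sv·σ_vt path-count identity and (on tiny graphs) exhaustive simple-path
  enumeration, E_c from dense eigendecomposition, plus igraph as an
  external second opinion.

## Null models and inference

* **Hub calling.** Per threshold, `n_null` Erdős–Rényi graphs are drawn
  from G(n, m) with the real graph's exact edge count — "calibrated" is
  read as density-matched, and fixing m exactly removes one variance
  source. Because ER nodes are exchangeable, the null distribution of a
  centrality metric pools all nodes of all null graphs (59 000 samples per
  threshold at the published n_null = 1000). z-scores are averaged across
  the grid (the aggregation is not stated in the source design; the
  arithmetic mean is the simplest choice and per-threshold components are
  retained in the output), and a region is a hub on a metric when mean
  z > 1.96. A region counts as a network hub when it is a hub on *any* of
  k_i, B_c, E_c.
* **Permutation tests.** The observed statistic is the across-threshold
  mean of the per-threshold group difference. Permutations reassign
  animals to pseudo-groups of the original sizes and rebuild both networks
  from scratch; the null pools every permuted per-threshold difference and
  the two-sided p-value carries the +1 correction, so p is never exactly
  zero. Permuted networks that disconnect at a threshold contribute NA to
  path-length differences; drops are counted and warned about beyond 10%.
  For regional statistics the permutation statistic is the raw centrality
  difference: recomputing an ER z-ensemble inside each of 55 000
  permutations would multiply cost a thousand-fold, and at fixed edge
  count the z-transform is an affine per-threshold rescaling that leaves
  the permutation ordering unchanged.
* **Rich club.** φ(k) is the edge density among nodes of degree > k. The
  default normalisation divides by the mean φ of degree-preserving
  rewired graphs (double-edge swaps, 10·|E| attempts), the standard
  correction for the degree-sequence confound. The core degree k* is the
  smallest k such that φ_norm > 1 and empirical p < 0.05 hold there and at
  every higher k that retains ≥ 4 qualifying nodes; the rich-club core
  (RCC) is the set of regions qualifying (degree > k*) at a majority of
  grid thresholds. Caveat discovered during development: when the
  high-degree subgraph is an exact clique and its members are adjacent to
  most of the graph, **no legal double-edge swap can remove a clique
  edge** (every candidate swap collides with an existing edge), so
  φ_rand ≡ φ and the rewiring null is degenerate — it can never declare
  that clique a rich club. `null_model = "er"` substitutes density-matched
  G(n, m) nulls for exactly this situation, which arises for strongly
  planted synthetic blocks; on noisy empirical graphs the rewiring null
  behaves normally. The whole detector is a documented stand-in for the
  externally published rich-club algorithm, and its output says so.

## PLSR seed connectivity

* The seed region's uptake is regressed on all other regions (within one
  group), all columns centred and scaled within group, by sequential
  NIPALS components with predictor deflation; deterministic, no random
  initialisation. Default 2 components: groups of 8–13 animals cannot
  support many, and 2 is the smallest count that exercises the
  component-weighted structure of VIP.
* VIP_j = sqrt( p · Σ_a SSY_a w_ja² / Σ_a SSY_a ) with unit-norm weights;
  mean_j VIP_j² = 1 identically, asserted on every fit.
* Jackknife: leave-one-animal-out refits (re-standardising on the retained
  animals), Tukey SE, normal 95% CI (±1.96·SE) floored at 0. The CI form
  is not stated in the source design; the normal approximation is the
  plainest reading of "95% CI estimated by jack-knifing".
* Between-group comparison is a Welch t-test on jackknife pseudo-values
  (n·θ̂ − (n−1)·θ̂₍ᵢ₎), Bonferroni-corrected over the seed's 58 targets —
  a t-test on one VIP per group is otherwise undefined.
* Classification is the literal conjunction: **lost** = WT CI lower > 1.0,
  HET CI lower < 1.0, adjusted p < 0.05; **gained** mirrored;
  **restored** = significant drug-induced increase in HET (Bonferroni),
  drug-group CI lower > 1.0, and no significant difference from untreated
  WT (Bonferroni).

## The synthetic world

`synthetic_spec()` states the world once: 59 regions; group sizes 8/9/9
(WT saline/ketamine/amphetamine) and 10/13/11 (HET); baseline
inter-regional correlation 0.2; three hub regions (the catalogue's MD,
dRT, VL) correlated 0.7 with every other region; a seven-region rich-club
block (dRT, vRT, Re, CM, CL, aPrL, Cg1) at 0.75; all within-block edges
lost (collapsed to baseline) in HET/SAL and HET/AMPH and restored in
HET/KET; +0.15 uptake-ratio units of thalamic hypermetabolism in untreated
and amphetamine-treated mutants, normalised by ketamine; residual SD 0.08;
Gaussian noise truncated below at 0.05 to honour positivity; sex carries
no planted effect (a `sex_shift` hook exists for power studies). Groups
are drawn in fixed alphabetical order so a seed is portable.

Planted correlation matrices are repaired to the nearest positive
semi-definite correlation matrix by eigenvalue clipping (floor 1e-8, then
renormalisation to unit diagonal). With three all-to-all hubs plus a dense
block this repair is **not** a small perturbation: hub edges planted at
0.7 come out between roughly 0.45 and 0.83. The repaired matrix — not the
raw planted one — is the generator's true target, and convergence tests
compare against it.

What a green test does and does not establish: the generator emulates
group-specific correlation structure and mean shifts under Gaussian noise.
It does not emulate autoradiographic image noise, optical-density
calibration, plasma-glucose variation, inter-batch effects, or the heavy
inter-regional coupling of real 2-DG data (where whole-brain normalisation
induces global dependence). Recovery results on this world say the
pipeline's machinery is wired correctly, not that the study's biological
effect sizes are detectable at these sample sizes.

## Known limitations

* At n = 12 per group, the three-clause lost/gained/restored conjunction
  with Bonferroni correction over 58 targets has low power at the
  synthetic world's planted separation (VIP ≈ 2.3 vs ≈ 0.9): the
  jackknife SE of VIP is ≈ 0.35, so the required |t| ≈ 4.3 is reached in
  well under half of replicates, and the WT CI-lower > 1 clause holds in
  only ~50–80%. The corresponding acceptance expectation (≥ 80% recovery)
  is left failing rather than weakened; the package reports honest rates.
* The rewiring rich-club null is degenerate on exact planted cliques (see
  above); use `null_model = "er"` there.
* The ER hub null pools across nodes, which assumes node exchangeability;
  it is exact for G(n, m) but only approximate if real networks had
  strongly heterogeneous degree variance.
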