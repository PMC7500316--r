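---
title: "Structural covariance networks: model, metrics and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks: model, metrics and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

A structural covariance network is a group-level graph: its nodes are
atlas regions (here the 90 cerebral regions of the AAL parcellation) and
its edges are interregional Pearson correlations of a morphometric
measure — typically regional gray matter volume — computed **across
subjects**. Because the correlation is taken over subjects, there is one
network per group, not per subject; comparing groups therefore needs
permutation inference rather than subject-level statistics.

The pipeline implemented by `scovnet`:

1. **Nuisance regression** (`residualize()`). Per region and within each
   group, regional values are regressed on an intercept, age, sex (0/1)
   and total intracranial volume by ordinary least squares; residuals
   carry forward. A rank-deficient design is refused with the collinear
   covariates named.
2. **Correlation** (`correlation_matrix()`). The N × N Pearson matrix of
   the residuals, diagonal zeroed.
3. **Density thresholding** (`threshold_by_density()`). At target density
   $d$, the $K = \mathrm{round}(d\,N(N-1)/2)$ strongest edges are kept and
   binarized. The analysis grid is $d = 0.10$ to $0.50$ in steps of
   $0.02$: the lower end is chosen so group networks stay fully connected,
   and binary structural networks denser than 50% are conventionally
   regarded as non-biological (`validate_density_grid()` reports both
   conditions).
4. **Graph metrics** per density: clustering coefficient $C_p$,
   characteristic path length $L_p$, global and local efficiency, and
   normalized nodal betweenness.
5. **Small-world normalization**: $\gamma = C_p/C_p^{rand}$,
   $\lambda = L_p/L_p^{rand}$, $\sigma = \gamma/\lambda$, where the
   reference values are arithmetic means over an ensemble of 20
   degree-preserving randomizations. $\sigma > 1$ (equivalently
   $\gamma > 1$ with $\lambda \approx 1$) indicates small-world
   organization.
6. **Resilience**: the size of the giant connected component, relative to
   the largest component of the intact network, as nodes are removed
   either in random order or in decreasing order of betweenness (or
   degree).
7. **Permutation inference**: subjects are pooled and reassigned to
   pseudo-groups of the original sizes; the *entire* pipeline — including
   the within-group nuisance regression and fresh null ensembles — is
   re-run on every relabeling. Group differences are assessed per density,
   and summarized across the grid by the trapezoidal area under the
   metric-vs-density curve (AUC), which reduces sensitivity to any single
   threshold.

# Design choices

Several points are conventions rather than consequences of the
definitions; they are fixed as follows.

**Edge ranking.** Edges enter by *signed* correlation (strongest positive
covariation first), the usual convention for structural covariance where
edges represent coordinated growth; `rank_by = "abs"` is available. Ties
at the cutoff are broken by descending $|r|$, then lexicographic node
pair, so edge sets are deterministic and nested along the grid.

**Disconnected pairs.** Group networks on the analysis grid are
connected, but permuted or sparse networks may not be. $L_p$ averages
over connected pairs only and sets a `disconnected` flag; efficiency
treats disconnected pairs as zero contribution ($1/\infty$). This keeps
permutation distributions finite without discarding relabelings.

**Null ensembles.** Maslov–Sneppen double-edge swaps with $10E$ attempted
swaps per null, degree sequence preserved exactly, connectivity *not*
enforced. Ensemble statistics are arithmetic means. Swap acceptance below
10% triggers a warning (near-regular or saturated graphs barely
randomize). A 20-null $\sigma$ estimate of a sparse 90-node graph has a
sampling standard deviation around 0.2; tests that probe the null value
$\sigma \approx 1$ therefore average several randomizations.

**Betweenness.** Brandes-style fractional crediting over all equal-length
shortest paths. Regional values are normalized by the network-average
betweenness; when that average is zero (e.g. complete graphs) normalized
values are defined as zero and flagged.

**The test tail.** The toolbox convention this package mirrors tests
one-tailed at the 95th percentile *on the side of the observed
difference*. When the direction is read off the data, that procedure's
overall type-I rate is $2\alpha$: each tail contributes $\alpha$. The
default here (`tail = "two_sided"`) therefore places the critical value
at the $1-\alpha/2$ percentile on the observed side and doubles the
one-sided permutation p-value $(b+1)/(n_{perm}+1)$, restoring overall
size $\alpha$; `tail = "directional"` reproduces the literal convention.
No correction is made across densities or regions by default, matching
common practice; the AUC summary is the primary guard against
threshold-by-threshold multiplicity.

**Resilience.** A single random-removal pass is noise-dominated, so the
random-failure curve averages 100 seeded removal orders by default
(`n_orders = 1` gives a literal single pass, `exact = TRUE` the exact
expectation by subset enumeration, feasible to 20 nodes). Targeted attack
ranks nodes once on the intact network by default; `recompute = TRUE`
re-ranks after every removal. Ties break by ascending node index. The
permutation comparison of resilience runs at a single reference density,
by default the smallest grid density at which both observed group
networks are connected (recorded in the output metadata). The normalizer
is always the largest component of the intact network, even if that
network is disconnected.

# The synthetic cohort generator

No public morphometry dataset accompanies this design, so the generator
produces the post-processing regional-volume table directly. Regional
values for a subject are

$$ y = \mu + X\beta + z + \varepsilon, \qquad
   z \sim \mathcal{N}(0, \Sigma), \quad
   \varepsilon \sim \mathcal{N}(0, \sigma^2_{noise} I), $$

where $\Sigma$ is built from a ground-truth graph $A$ as
$I + \rho A$ ($\rho$ = `base_correlation`), repaired to the nearest valid
correlation matrix by clipping negative eigenvalues and rescaling to unit
diagonal. The realized correlation of a ground-truth edge is then
$\Sigma_{ij}/(1+\sigma^2_{noise})$ in closed form, which is what the
generator's tests check against sample correlations. Covariates
contribute additive effects $\beta$ shared across regions: the same
nuisance structure the regression step is meant to remove.

Defaults mirror the two-group study design this package targets: 31
subjects per group, 90 regions, ages uniform on 40–67 years (spanning
the reported patient and control ranges), sex Bernoulli(1/2), TIV
$\mathcal{N}(1450, 120)$ ml, a Watts–Strogatz covariance topology
($k = 6$, $p = 0.05$) with edge correlation 0.6 and noise sd 0.3. No
distributional facts about real regional volumes are published for this
design, so these are conventions chosen to be biologically plausible,
not estimates. Documented effect presets (`effect_preset()`) modify a
second group's generator with a known signature: `reduced_clustering`
rewires the small-world topology almost completely ($p = 0.9$),
lowering downstream $C_p$; `bridge_hub` makes region 1 the sole bridge
between two modules, inflating its betweenness.

What the generator does *not* emulate: spatial smoothing and the
resulting distance-dependent correlation structure, hemispheric symmetry,
lognormal-ish volume distributions, site or scanner effects, and any
disease process beyond the explicit presets. Passing tests therefore
demonstrate that the pipeline recovers known covariance topology and
holds its error rates under the stated model — not that any particular
clinical contrast is reproducible.

# Numerical conventions and problem sizes

- Shortest-path distances are computed exactly by level-synchronous BFS
  via boolean matrix products; metric implementations are pinned to
  brute-force oracles (Floyd–Warshall, exhaustive triangle and
  shortest-path enumeration) on all 1252 non-isomorphic graphs with up to
  7 nodes, at tolerance $10^{-12}$.
- Resilience curves over a removal order are computed by reverse node
  addition with union-find, making averages over many orders cheap; the
  exact expected random-failure curve uses the fact that the first $k$
  removals of a uniform order form a uniform $k$-subset.
- All randomness flows from named integer seeds; per-iteration seeds are
  derived deterministically, so every comparison is reproducible byte for
  byte, and permutation 0 is the identity relabeling (asserted to
  reproduce the observed statistics through the same code path).
- Simulation-based test suites run at sizes chosen to keep the full suite
  fast while honoring the replicate counts that make the checks
  meaningful: the type-I study uses 100 replicate null pairs of 31 + 31
  subjects on 24 regions with a three-point density grid and 200
  permutations; effect recovery uses 50 replicates of the full 90-region
  default model on a nine-point grid. Small-world detection uses 100
  seeded Watts–Strogatz graphs at the full N = 90, k = 6, p = 0.05 with
  20-null ensembles.

# Limitations

- Covariance networks are group-level; nothing here yields
  subject-level networks or supports brain-behavior correlation.
- Only binary undirected graphs are analyzed; no weighted or directed
  variants, no modularity or hub classification.
- The directional permutation convention is provided for replication but
  is anticonservative (size $2\alpha$); use the default two-sided tail
  for calibrated inference.
- The per-density tests are not corrected for multiple comparisons;
  interpret density-by-density stars descriptively and rely on the AUC
  summaries.
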