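---
title: "Methods: MSAP scoring and distance-based epigenetic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSAP scoring and distance-based epigenetic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Methylation-sensitive amplified polymorphism (MSAP) digests genomic DNA in
parallel with two isoschizomers of the 5′-CCGG-3′ motif, HpaII and MspI,
whose cutting is blocked by different CpG-methylation configurations.
After selective amplification and capillary electrophoresis, each fragment
locus yields a presence/absence bit per digest, and the bit pair encodes a
categorical methylation state: (1,1) non-methylated (NMT), (1,0)
hemimethylated (HMM), (0,1) internal cytosine methylation (ICM), and (0,0)
read conservatively as hypermethylation (HPM). The (0,0) reading is the
key interpretive assumption: joint absence can also arise from sequence
variation at the cut site, so treating it as methylation overstates
methylation wherever fragment presence is genetically polymorphic. We keep
the conservative coding (it is the standard in ecological MSAP work and
retains the most informative fraction of the data) and expose no
alternative; analyses that want to exclude (0,0) can drop HPM columns from
the one-hot encoding.

`classify_states()` is a total function on \{0,1,NA\}² — any NA in either
digest yields MISSING, and the four states partition the remaining pairs —
so scoring can never silently invent data.

## Scoring parameters

| parameter | default | units | role |
|---|---|---|---|
| `size_min`, `size_max` | 50, 1500 | bp | fragment-size scoring window (inclusive) |
| `rfu_min` | 40 | RFU | peak intensity filter, strict `>` |
| `bin_width` | 1.0 | bp | locus bin width, bins centred on integer sizes |
| `min_prevalence` | 0.15 | fraction | locus retained if present in ≥ 15 % of samples (inclusive) |
| `meth_threshold` | 0.05 | fraction | locus is methylation-susceptible (MSL) if its methylated-state fraction strictly exceeds this |

Capillary genotyping software reports fragment sizes to sub-bp precision
but scores discrete loci; since no binning rule travels with exported peak
tables, we bin at fixed 1 bp width anchored at integer sizes. This is the
finest binning consistent with typical size-calling error; wider bins can
be configured when run-to-run size drift is larger. The prevalence filter
is applied to fragment presence pooled across the two digests (a locus
"exists" if either digest amplifies it); a per-digest variant is available.
We filter prevalence *before* state classification because it is part of
the peak-scoring stage, and we assess polymorphism *after* the (0,0)→HPM
coding, i.e. on states, since that is the substrate of every downstream
analysis. The MSL threshold (5 %) follows the usual error-threshold
convention for separating methylation-susceptible loci from loci whose
rare methylated calls are indistinguishable from scoring error.

Missing cells (NA) are kept distinct from 0 throughout — (0,0) is HPM,
analytically meaningful — and are imputed (feature-wise mean) only at the
numeric encoding step, never during state counting or diversity
estimation, so frequency-based quantities are computed on scored cells
only.

# Diversity

Per-locus Shannon diversity is computed over the four state frequencies
among scored samples, in nats (0 ≤ H ≤ ln 4 ≈ 1.386), and aggregated as
mean ± SD **across loci**. The locus-wise reduction is the default because
the index quantifies heterogeneity *within* methylation-susceptible loci;
a sample-wise reduction is available (`by = "sample"`) since the
aggregation direction is a genuine convention choice. The logarithm base
is configurable; natural log is the default convention.

# Distance-based statistics

All distance machinery is implemented in-package from the Gower identities
(with `vegan` used as an independent oracle in the test suite, never as
the implementation): writing $A = -\tfrac12 d^2$ and
$G = (I - \mathbf{1}\mathbf{1}'/n)\,A\,(I - \mathbf{1}\mathbf{1}'/n)$,
the total sum of squares is $\mathrm{tr}(G)$ and the portion explained by
a model with hat matrix $H$ is $\mathrm{tr}(HG)$.

- **PERMANOVA** uses sequential (Type I) sums of squares in the
  user-given term order, because the study design reports separate site
  and season fractions that sum with a combined value. Significance is by
  free permutation of sample labels,
  $p = (1 + \#\{F^\pi \ge F\})/(1 + n_\pi)$, with 999 permutations by
  default and a mandatory-seed discipline for reproducibility. An
  exhaustive mode enumerates all $n!$ label orders for $n \le 9$; its
  p-value equals enumeration over distinct group splits (each split
  appears equally often), which the tests verify against a brute-force
  oracle built from the classic within-group sum-of-squares formula.
- **PERMDISP** embeds samples by principal coordinates keeping negative
  eigenvalue axes as an imaginary part, measures each sample's distance
  to its group centroid as $\sqrt{d^2_{\text{real}} - d^2_{\text{imag}}}$
  (clamped at zero), and permutes the resulting dispersion distances under
  a one-way F statistic.
- **PCoA** eigendecomposes $G$; negative eigenvalues (non-Euclidean
  distances) are dropped by default, with the Lingoes additive correction
  optional, and explained fractions are relative to the sum of retained
  positive eigenvalues. On Euclidean distances PCoA equals PCA up to axis
  sign, which the acceptance tests check to 1e-8.
- **dbRDA** regresses the positive-axis PCoA coordinates on the predictor
  table; the constrained fraction is constrained over total inertia, and
  both the overall and the sequential per-term pseudo-F are tested by
  permutation (label permutation by default).

The default distance for methylation matrices is **Euclidean on the
methylated/non-methylated binary encoding** (`METH_BINARY`). The source
analyses do not state a metric; Euclidean keeps PCoA exact (no negative
eigenvalues) and matches common MSAP practice. Jaccard and simple-matching
metrics, and a four-state one-hot encoding, are available when the
distinction between methylated states matters downstream.

# DAPC and influential loci

`fit_dapc()` reduces the encoded matrix to $k-1$ principal components
(the convention for $k$ groups) and extracts up to two discriminant axes
from the generalized eigenproblem of between- versus within-group scatter
of the PC scores, solved by Cholesky whitening; a singular within-group
scatter is ridge-stabilized ($10^{-6}$ of the mean diagonal) with a
warning. Group labels are always supplied a priori from the significant
design factors — no unsupervised k-selection. Feature loadings are
back-projected through the PCA rotation and reported as squared, axis-wise
normalized contributions summing to 1 per axis, which makes the
influential-locus percentile rule scale-free. `select_influential()`
implements the 90th-percentile rule (ties at the threshold all included)
and, as an alternative, a threshold-free above-mean rule. The two rules
select very different fractions (≈ 10 % versus typically 20–40 %); since
no stated rule reproduces the ~48 % "most influential" fraction reported
in the motivating analyses, neither is asserted to, and the percentile
rule is the default because it is the one defined explicitly.

# Plasticity coupling

For paired sample groups — by default, each site's dry-season versus
wet-season group — the statistic pairs (i) the Euclidean distance between
group centroids in PCoA methylation space (all positive axes by default,
since no axis count is canonical) with (ii) the absolute difference in
mean log(x+1) righting time, and rank-correlates the two lists with
Spearman's rho (average-rank ties). The phenotype axis is univariate
righting time by default; a multivariate option adds log test diameter.
Because the number of pairs is small, p-values use the exact permutation
distribution for up to 8 pairs and the t-approximation beyond; fewer than
3 pairs returns an explicitly flagged undefined rho rather than a NaN.
Besides the within-site pairing, `across_status` (transplant designs) and
`all_pairs` (site-combination centroids) pairings are provided, since both
readings of the original figure are defensible.

# Field metrics

Sedimentation rate is mass/(trap-opening area × days) with the 6.4 cm
aperture default; N:P status uses ratio ≤ 16 as nitrogen-limited
(inclusive, per the stated interval), 16–22 as transition (22 inclusive),
and > 22 as phosphorus-limited; seasons are January–April (dry) and
May–November (wet) with December undefined and rejected; size classes are
< 40 mm, 40–60 mm inclusive, > 60 mm. Monthly survival rates chain
(SR$_t$ = N$_t$/N$_{t-1}$) so their product telescopes to the terminal
fraction; the population-level estimate is the simple (unweighted) mean of
monthly SRs, the natural reading of "monthly rates averaged" — a
cohort-size-weighted mean would equal the terminal-fraction estimator and
is easily obtained from the returned table.

# The synthetic generator

The generator emulates the structure of the motivating monitoring study,
with defaults fixed once:

- 3 sites × 2 seasons × 14 samples (84 DNA samples; the study's fourth
  site was excluded from tissue sampling) and 300 fragment loci;
- per-locus state frequencies drawn from a Dirichlet with mean
  NMT .10 / HMM .25 / ICM .15 / HPM .50 and concentration 1.0 —
  hypermethylation-predominant on average, strongly skewed per locus so
  per-locus Shannon diversity is right-skewed and a small percentage of
  loci come out monomorphic (~98 % polymorphic), as in real MSAP data;
- a seasonal effect on 20 % of loci: in the wet season an affected cell's
  state is replaced with probability 0.3 (the `effect_size`) by a
  locus-specific target state drawn from the states *other than* the
  locus's modal state — a target equal to the modal state would produce no
  realized shift and make "affected" vacuous;
- site effects with the same mechanism but 10× weaker
  (`site_effect_ratio = 0.1`), each site-affected locus shifting in one
  randomly chosen site;
- exact inverse mapping of states to digest pairs, then digest-bit flips
  at `noise_rate = 0.02` (a typical AFLP/MSAP scoring error), so the
  scoring stage — not just the statistics — is exercised;
- phenotypes on the log(x+1) scale: baseline ≈ 10 s righting time, small
  site/season effects, a positive sedimentation slope (0.01 log-s per
  mg·cm⁻²·day⁻¹ over the default site regimes 33.4/14.3/6.2/3.6), and a
  diameter component whose coefficient is solved from the realized
  variance of the remaining components so the marginal Spearman
  correlation with test diameter approaches the 0.3 target at large n;
- caged survival as monthly binomial thinning (cohorts of 14, controls of
  5 in the emulated design);
- `gen_coupled_groups()` builds the plasticity-coupling test bed: each
  site's seasonal epigenetic shift magnitude and its righting-time shift
  are lognormal transforms of latents correlated at the coupling strength
  (six sites, five epigenetic features, within-group SD 0.2, latent log-SD
  0.75 — shifts well separated from centroid-estimation noise at ten
  samples per group).

What passing these tests does *not* show about real data: the generator
draws cells independently given the locus priors — it has no linkage
between loci, no genetic (fragment-loss) component inside the (0,0) class,
no size-calling drift between runs, and its effects are state-replacement
mixtures rather than graded intensity changes. Power and calibration
results under the generator therefore validate the machinery, not
field-data effect sizes.

# Problem sizes and numerical choices

The test suite sizes its simulations for a single-CPU run: calibration
(type-I error) uses 500 replicates of 24 samples × 40 loci with 999
permutations for both PERMANOVA and dbRDA; power uses 100 seeds of the
2-site × 2-season, 20-samples-per-group, 200-locus condition; coupling
recovery uses 100 seeds at coupling 0.9 and 100 at 0. The power
comparison of season versus site R² uses a two-site design so both terms
carry one degree of freedom — raw R² comparisons across terms with unequal
df are confounded by the larger term's null expectation.

Other numerical conventions: permutation p-values always include the
observed statistic in the numerator and denominator (never exactly zero);
exhaustive enumeration includes the identity; comparisons against
permuted statistics use a 1e-12 slack so ties count as "as extreme";
quantile thresholds use the default empirical quantile (type 7) with ties
at the threshold all selected; DAPC axis signs are arbitrary and all tests
compare up to sign; all-zero distance matrices, empty peak tables,
all-MISSING loci, and single-level factors are handled with explicit
warnings or named errors rather than NaNs.

# Limitations

- Restricted/stratified permutation schemes (e.g. permuting within sites)
  are not implemented; all tests use free exchange.
- dbRDA offers no partial (conditioned) analysis.
- GLM-based environmental modelling, ANOVA/Tukey machinery, and effect
  sizes are deliberately out of scope — standard tools cover them; this
  package produces the derived metrics those models consume.
- Raw electropherogram (.fsa) processing and fragment-size calling are out
  of scope; the pipeline starts from exported peak tables.
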