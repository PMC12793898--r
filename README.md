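# epimsap

Epigenetic analysis of **methylation-sensitive amplified polymorphism
(MSAP)** fingerprints for ecological studies, built around the monitoring
and transplant designs used for reef invertebrates such as the long-spined
sea urchin *Diadema antillarum*.

MSAP profiles a genome's 5′-CCGG-3′ sites with two isoschizomers that share
a cut site but differ in CpG-methylation sensitivity (HpaII, MspI). The
presence/absence pattern of each fragment across the two digests encodes a
methylation state:

| HpaII | MspI | state | meaning |
|-------|------|-------|---------|
| 1 | 1 | NMT | non-methylated |
| 1 | 0 | HMM | hemimethylated (one strand) |
| 0 | 1 | ICM | internal cytosine methylation |
| 0 | 0 | HPM | hypermethylated (conservative reading of joint absence) |

The package covers the full analysis chain:

- **Scoring** — capillary-electrophoresis peak tables → binary fragment
  matrices (50–1500 bp window, intensity > 40 RFU, ≥ 15 % sample
  prevalence), the state truth table above, and the partition into
  methylation-susceptible loci (MSL: methylated-state fraction > 5 %).
- **Diversity** — per-locus Shannon index H = −Σ p_s ln p_s over the four
  state frequencies, and grouped state-frequency profiles.
- **Multivariate statistics, implemented from first principles** —
  PERMANOVA (sequential sums of squares from the Gower-centered
  inner-product identity, free label permutation), PERMDISP, PCoA, RDA
  variance partitioning, and distance-based RDA (dbRDA) of methylation on
  log-transformed physiological metrics.
- **DAPC** — PCA reduction (k − 1 PCs by default) followed by linear
  discriminant axes, with loadings back-projected to loci and an
  influential-locus rule (90th percentile of loading contributions).
- **Plasticity coupling** — Spearman rank correlation between group-pair
  centroid distances in PCoA methylation space and the corresponding
  absolute differences in mean log(x+1) righting time.
- **Field metrics** — sediment-trap deposition rate, molar N:P
  nutrient-limitation status (16 / 22 thresholds), dry/wet season
  classification, urchin size classes, belt-transect densities, and chained
  monthly survival rates SR = N_f / N_i.
- **Synthetic data with known truth** — generators for two-digest fragment
  profiles (HPM-predominant, seasonal effects an order of magnitude
  stronger than site effects), phenotypes (righting time rank-correlated
  with test diameter, slowed by sedimentation), caged survival series, and
  coupled group-level epigenetic/phenotypic shifts.

## Worked example

```r
library(epimsap)

sim <- gen_msap(sim_config(seed = 11))          # 84 samples, 300 loci
fm  <- filter_prevalence(sim$fragments)         # >= 15% prevalence
sm  <- partition_msl(classify_states(fm))       # states + MSL partition
sm
#> MSAP state matrix: 84 samples x 249 loci
#>   states:  NMT 12.1%  HMM 29.6%  ICM 19.0%  HPM 39.2%  MISSING 0.0%
#>   MSL: 249 (100.0%), of which polymorphic: 249 (100.0%)

shannon_diversity(sm)
#> Shannon diversity over methylation states (locus-wise, n = 249)
#>   mean +/- SD: 0.784 +/- 0.243  (max possible 1.386)

d <- pairwise_distances(encode_matrix(sm, "METH_BINARY"))
permanova(d, ~ site + season, sim$meta, permutations = 999, seed = 1)
#> PERMANOVA (sequential SS, 999 permutations of sample labels)
#>      term df        SS      R2      F     p
#>      site  2   29.5714 0.02085 0.8795 0.897
#>    season  1   44.1429 0.03112 2.6260 0.001
#>  Residual 80 1344.8600 0.94800     NA    NA
#>     Total 83 1418.5700 1.00000     NA    NA
```

Methylation profiles separate by season (R² ≈ 3 %, p = 0.001) while the
site term stays at its permutation-null baseline — the generated (and
observed) pattern that seasonal environmental change, not location, drives
the epigenome. Downstream, `pcoa()` embeds the distance matrix,
`fit_dapc()` + `select_influential()` rank loci driving the separation, and
`plasticity_coupling()` relates per-site seasonal methylation shifts to
righting-time shifts.

`run_pipeline("run.yaml")` chains every stage (scoring → diversity →
PERMANOVA/PERMDISP → PCoA → dbRDA → DAPC → plasticity), writing one report
file per stage plus a `manifest.json` with config, seeds and file digests;
re-running the same config reproduces all outputs bit-identically.

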