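# gradloc

Proportional subcellular localization of RNA and protein from
density-gradient fractionation profiles.

## The problem

Where a transcript or protein sits in the cell — nucleus, nucleolus, ER,
mitochondria, cytosol, or cytosolic RNP granules — determines what it can
do, and relocalization (for example during the unfolded protein response,
UPR) is a core regulatory layer. Equilibrium density-gradient fractionation
followed by RNA-seq and multiplexed (TMT) proteomics measures, for every
molecule, a *fraction profile*: its relative abundance across the gradient
fractions. The fractions are not purified organelles; localization must be
inferred from the shape of the profile. `gradloc` implements the full
computational path from fraction-level quantifications to per-molecule
localization **proportions**, for analysts working with such gradient
experiments.

## The model

Spike-in features added at a fixed absolute amount to every fraction library
recover the per-fraction RNA content that library normalization destroys:

    content_f  ∝  (endogenous_f / spikein_f) / proportion_used_f

After content adjustment and row normalization, a transcript's profile
`x ∈ R^F` (F fractions, `Σ x_f = 1`) is modeled as a non-negative linear
combination of the mean profiles `b_l` of each localization's markers, plus
a sign-unconstrained intercept c:

    min_{p ≥ 0, c}  || x − Σ_l p_l b_l − c·1 ||²

`p_l` is the proportion of the molecule in localization *l*. Fits are kept
only when R² ≥ 0.90 and |c| ≤ 0.05, replicate estimates are averaged when at
least 2 of 3 replicates pass, and uncertainty comes from resampling markers
within each class (100 bootstrap rebuilds of the basis). The 13
mitochondrially encoded mRNAs, which have no cytosolic copies, anchor 100%
membrane localization. Marker classes themselves are discovered
semi-supervised: a priori enrichment rules (nuclear/cytoplasm fractionation,
APEX proximity labeling, ER ribosome profiling + signal-peptide/TM
annotation) are expanded to full non-negative matrix factorization clusters,
with the NNMF rank chosen by imputation of held-out entries — which is how
the granule ("cytosol light") class emerges as a cluster containing few a
priori markers.

The proteomics arm processes PSM-level reporter intensities (contaminant
propagation through shared peptides, missingness filtering, profile-space
knn imputation, median-distance outlier removal, median centering, ≥2-PSM
protein aggregation), classifies proteins against marker profiles with a
grid-searched SVM, and tiers differential-localization calls from posterior
probabilities (localization assigned when `p_loc·(1 − p_out) > 0.95`;
relocalization tiers at ≥0.99 / ≥0.95 / ≥0.85 in ≥2 of 3 replicates).
Downstream feature models — elastic net with shared cross-validation folds
and one-standard-error lambda, and a shrinkage cubic-spline GAM whose
residuals measure stress-resistant membrane retention — relate localization
changes to transcript features (length, AU content, k-mers, codons,
upstream AUGs, RBP binding).

Everything is testable against a bundled synthetic fractionation simulator
with known ground truth (localization archetypes, spike-ins, negative
binomial counting noise, logistic granule relocalization, planted PSM
contaminants/outliers/missingness).

## Worked example

```r
library(gradloc)

locs <- c("nucleus", "nucleolus", "cytosol", "cytosol_light",
          "er", "mitochondria")
ark <- generate_archetypes(locs, fraction_count = 8, seed = 1)
cfg <- sim_config(n_transcripts = 1000, seed = 42)
ds  <- simulate_rna_experiment(cfg, ark)

res <- recover_proportions(ds)   # content -> normalize -> basis -> NNLS
res$proportions[1:4, c("feature_id", "condition", locs[c(1, 3, 5, 6)])]
#>   feature_id condition nucleus cytosol      er mitochondria
#> 1 TX00001    control     1.02  0.0111  0.00970      0.00885
#> 2 TX00001    upr         0.954 0.00554 0.00574      0.00444
#> 3 TX00002    control     0.961 0.00319 0.00322      0.00310
#> 4 TX00002    upr         0.987 0.00340 0.00228      0.00293
```

TX00001 is a pure nuclear marker: its estimated nuclear proportion is ~1 in
both conditions (proportions are not forced to sum to 1; small off-target
loadings reflect counting noise). Against the simulator's ground truth:

```r
#> mean absolute proportion error vs truth: 0.011
```

Granule relocalization under stress is biotype-specific by construction,
and the recovered deltas show it:

```r
delta <- relocalization_delta(
  res$proportions[res$proportions$condition == "control", ],
  res$proportions[res$proportions$condition == "upr", ],
  "cytosol_light")
#> median granule gain under stress: mRNA 0.392, lncRNA 0.003
```

mRNAs move into granules in a length/AU/membrane-prior-dependent way;
lncRNAs stay put.

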