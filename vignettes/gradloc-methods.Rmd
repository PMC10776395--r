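---
title: "Methods: proportional subcellular localization from gradient profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proportional subcellular localization from gradient profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradloc)
```

# The measurement and its model

Equilibrium density-gradient fractionation distributes every RNA and protein
across F gradient fractions according to the density of the structures it is
attached to. A molecule present in several compartments produces a *mixture*
profile. gradloc's central assumption is linearity of that mixture: if a
transcript has a proportion $p_l$ of its copies in localization $l$, and the
paradigmatic profile of localization $l$ across the fractions is
$b_l \in \mathbb{R}^F$ (row-normalized), then the transcript's
row-normalized profile is

$$x \approx \sum_l p_l\, b_l + c\,\mathbf{1}, \qquad p_l \ge 0 .$$

The basis profiles $b_l$ are mean profiles of *markers*, molecules of known,
near-exclusive localization; they are correlation signatures, not purified
compartments, so proportions are always relative to what the markers
represent. The intercept $c$ is sign-unconstrained and absorbs uniform
background; it is realized inside the non-negative least squares solver by
augmenting the design with $+\mathbf{1}$ and $-\mathbf{1}$ columns, with
$c$ the difference of the two non-negative coefficients. Proportions are
*not* forced to sum to one during fitting; a normalized view is available
for ternary displays.

A fit is trusted when it explains the profile and needs no large offset:
$R^2 \ge 0.90$ (total sum of squares about the profile mean — "variance
explained" in the literal sense) and $|c| \le 0.05$ (on the row-normalized
scale, where a typical entry is $1/F$). Replicates are fit independently
and averaged when at least 2 of 3 pass. Uncertainty comes from resampling
each marker class with replacement (same size as the class, preserving
class balance), rebuilding the basis and refitting, 100 times by default;
the reported point estimate is the full-marker fit, not the bootstrap mean.

Two basis modes reflect two fractionation designs. In **density** mode the
gradient does not separate ER from mitochondria and ER markers relocalize
under stress, so the ER class is excluded and the mitochondrial class —
mitochondrially encoded mRNAs have no cytosolic copies — is relabeled
*membrane* and anchors 100% membrane localization. In **sedimentation**
mode mitochondria and ER are separate basis rows and membrane proportions
are their sum.

## Spike-in recovery of per-fraction content

Library preparation normalizes away how much RNA each fraction contained.
Spike-ins added at a fixed absolute amount per fraction library undo this:

$$\mathrm{content}_f \propto \frac{\mathrm{endogenous}_f/\mathrm{spikein}_f}
{\mathrm{proportion\ used}_f},$$

normalized to sum 1 (only relative content matters downstream). Profile
tables carry endogenous-scale quantifications with spike-in totals stored
alongside on the same per-million scale, which keeps the adjustment exact in
the noiseless limit. `normalize_profiles()` multiplies by content and
row-normalizes; it is idempotent on already-normalized input with uniform
content.

# Marker discovery

A priori markers come from rule conjunctions on user-supplied evidence
tables: nucleus, > 16-fold enrichment in nuclear/cytoplasm fractionation
RNA-seq (or a manual nuclear lncRNA list); cytosol, significant enrichment
in NES-targeted proximity labeling (or a manual list); ER, ribosome
profiling enrichment $> 2^{0.5}$ *and* significant > 8-fold enrichment in
ER-targeted proximity labeling *and* an encoded signal peptide or
transmembrane domain; mitochondria, the 13 mitochondrially encoded mRNAs
(bundled in `mito_mrna_markers()`).

These seeds are expanded by semi-supervised non-negative matrix
factorization of the row-normalized profiles. The solver is classical
multiplicative updates from a seeded random start (3 restarts, 500
iteration cap, relative-objective stop), with an observation mask so that
held-out entries do not drive the fit. The rank k is chosen by imputation:
hold out 5% of entries, factorize, score the mean squared error of
reconstructing the held-out entries; by default 10 independent masks are
averaged per candidate (a single 5% mask is too variable to rank
candidates reliably). Ties are broken toward the *smallest* rank within
$10^{-4}\,\overline{x^2}$ of the minimum MSE: on an exactly low-rank matrix
every rank at or above the generating one reconstructs to solver precision
(relative differences around $10^{-6}$), while noise-driven gaps between
ranks are at least an order of magnitude above the tolerance, so the
tie-break returns the generating rank without affecting noisy selection.

Each a priori set is mapped to its maximal-overlap cluster and the *entire*
cluster becomes the marker set (ties and two-localizations-one-cluster
conflicts are errors requiring curation). Clusters claimed by no
localization are reported as novel; the intersection of the novel clusters
found independently in basal and stress conditions defines the granule
("cytosol light") class. Nucleolus markers are the nuclear cluster
intersected with the top 30 most abundant snoRNAs. Gene-level markers
extend to transcripts whose transcript biotype matches the gene biotype;
irreproducible manual curation is expressed as an explicit blacklist file
rather than code.

# Proteomics processing

PSM tables are processed in a fixed order with documented defaults:
contaminant removal propagates through shared peptides (any master protein
sharing an observed peptide sequence with a cRAP protein loses all its
PSMs); PSMs without a unique master or with more than 20% missing reporter
values are excluded; remaining missing values are knn-imputed (k = 10) in
sum-normalized profile space — the distance is the mean squared difference
over channels observed in both rows, so neighbors share profile *shape*,
not average abundance — and de-normalized by the row's observed total so
observed entries are restored exactly; outlier PSMs with a median Euclidean
profile distance over 0.2 to their siblings are removed (literally: both
members of a discordant 2-PSM pair go, and the protein then fails the
two-PSM rule); channels are median-centered divisively (each channel
divided by its median, rescaled by the geometric-mean median — profiles are
later row-normalized, which makes divisive and subtractive centering on the
log scale nearly equivalent); proteins with at least two PSMs are summed
and row-sum normalized per replicate.

Marker-based classification uses a radial-basis SVM with stratified 80:20
splits, a small log-spaced cost/gamma grid tuned by 5-fold CV on the
training markers, per-class F1 on the held-out markers, 50 iterations by
default. Differential localization consumes posterior probability tables:
a protein is assigned a localization only when
$p_{loc}(1 - p_{out}) > 0.95$ (else "undefined"), and is called
differentially localized at tier highly-confident / confident / candidate
when at least 2 of 3 replicates have differential-localization probability
$\ge 0.99 / 0.95 / 0.85$ *and* the protein is never assigned the same
localization in the two conditions (matching "undefined" does not count as
the same localization). Exclusively nuclear proteins (knowledge-base score
5 for nucleus, nothing else above 2) split into profile groups by
thresholds applied in printed order, first match wins.

# Feature models

The relocalization models take a feature matrix assembled from sequences
and annotation: log10 lengths (transcript, 5'/3' UTR, CDS), k-mer
frequencies (overlapping windows; the full $4^k$ block sums to 1 per
sequence), AU content, abundance, binary RBP-binding columns (RBPs kept
when bound targets within the universe are strictly above the threshold),
upstream AUG counts split by frame (in-frame when the distance to the
annotated CDS start is a multiple of 3), codon / wobble / dinucleotide
frequencies, a MILC codon-optimality score (implemented from its original
definition, with a half-count pseudocount on reference codon counts so
divergence from codons the reference never uses still registers), binary
annotation flags, a one-hot encoding of the basal localization (argmax
proportion), and one-hot × length and one-hot × RBP interactions.

Penalized fits follow a fixed protocol: 80:20 train/test split, 10-fold CV
folds precomputed once and shared across the whole $\alpha$ grid
(0 to 1 in steps of 0.1) so mixing values are compared on identical
resamples, $\alpha$ at the minimum mean CV error, $\lambda$ by the
one-standard-error rule (largest $\lambda$ with mean error within one SE of
the minimum — `select_lambda_1se()` is exposed and tested against an
exhaustive scan), predictors standardized internally with coefficients
returned on the original scale, and the held-out 20% scored by ROC AUC
(logistic) or MSE (linear). Binary cytosolic labels use the two bands the
design defines ($\ge 2/3$ cytosolic, $< 1/3$ not); mid-band transcripts are
*excluded* rather than coded 0, since neither band's definition covers
them.

Stress-resistant membrane retention is the residual from a GAM of stress
membrane proportion on control membrane proportion with a cubic regression
spline with shrinkage (`bs = "cs"`). Smoothness is selected by REML — on an
exactly linear input REML recovers it to machine precision where GCV leaves
residuals near $3\times10^{-8}$; an exactly constant response makes the
REML scale estimate collapse, and the fit falls back to GCV, which handles
that limit. Group effects on top of the smooth are tested by refitting both
nested models with maximum likelihood (required when comparing fixed
effects between nested additive models) and an explicit F test; a
numerically negative deviance change is clamped to zero effect. Under a
null indicator the p-values are uniform to Kolmogorov–Smirnov scrutiny.
Residual-on-RBP models are lasso fits run separately for transcripts with
and without signal peptides/TM domains.

# The synthetic experiment

The simulator exists so that every stage has a recoverable answer. It
emulates: unimodal localization archetypes over 8 fractions — triangular
bands whose peaks cluster in pairs within shared density bands (as real
gradients band: nucleolus with nucleus, ER with mitochondria) over a 2%
uniform smear. The banded layout is not cosmetic: evenly tiled equal bumps
put the constant vector inside the basis row span, making the deconvolution
intercept unidentifiable and the $|c| \le 0.05$ filter reject well-fit
profiles; clustered unequal bands keep it identifiable, as real marker
profiles do. Ground-truth proportions are Dirichlet draws with
biotype-dependent concentrations (mRNAs weighted toward cytosol and ER,
lncRNAs confined to the nucleus:cytosol axis); markers are pure
single-localization anchors, exempt from relocalization. Expected
abundances are `abundance × (proportions · archetypes) × content ×
library factor`, spike-ins enter at a fixed absolute amount per fraction
before library scaling, and counts are negative binomial (dispersion 0.02
— within-profile noise is technical counting noise on libraries from one
homogenate; biological variability enters between replicates) at a depth
of 5 × 10⁶ per fraction library. In the stress condition mRNAs gain
granule mass with probability
$\mathrm{expit}(b_0 + b_1\log_{10}L + b_2\,\mathrm{AU} + b_3\,p_{mem})$,
drawn from their cytosol and ER mass; lncRNAs do not move.

The per-fraction `content` multiplier models recovery/volume differences
and defaults to *uniform*: the content differences the spike-in adjustment
must undo are emergent from where the transcriptome localizes (most RNA
mass sits in the nucleus/cytosol bands), and a non-uniform recovery
multiplier would additionally distort proportions relative to the marker
basis — a real effect of the measurement, available through the config,
but not part of the default study conditions, whose end-to-end identity
(noiseless simulation → pipeline → true proportions to $10^{-6}$) is a
tested invariant.

The PSM simulator plants cRAP contaminants, endogenous proteins sharing a
contaminant peptide, displaced outlier PSMs (alien archetype profile; at
most one per protein and only in proteins keeping ≥ 3 clean PSMs, so the
median-distance rule isolates exactly the plant), and intensity-dependent
missingness (logistic in standardized log intensity, calibrated to the
configured overall rate — MS left-censoring, so knn imputation is
meaningfully exercised).

What the simulator does **not** emulate: fraction pooling before
sequencing (profiles are emitted already pooled), read- or spectrum-level
noise (no FASTQ/spectra), isoform structure within genes, correlated
biological replicate effects, batch effects, or marker misannotation.
Passing tests therefore demonstrate correctness of the estimators under
the stated error model, not robustness to annotation error or to profile
shapes outside the linear-mixture assumption.

# Default parameters at a glance

| parameter | default | meaning |
|---|---|---|
| fractions F | 8 | pooled gradient fractions |
| replicates | 3 | per condition |
| dispersion | 0.02 | NB counting noise (technical libraries) |
| library size | 5e6 | expected counts per fraction library |
| spike-in share | 1% | of a typical library |
| R² threshold | 0.90 | minimum variance explained |
| intercept bound | 0.05 | on the row-normalized profile scale |
| replicate rule | 2/3 | passing replicates to report a feature |
| bootstrap B | 100 | marker resamples |
| NNMF holdout | 5% ×10 masks | imputation-based rank selection |
| knn k | 10 | PSM imputation neighbors |
| outlier distance | 0.2 | median profile distance between sibling PSMs |
| PSM missing cap | 20% | strictly-more removal rule |
| assignment threshold | 0.95 | on p_loc (1 − p_out) |
| DL tiers | 0.99/0.95/0.85 | in ≥ 2/3 replicates |
| α grid | 0–1 by 0.1 | elastic-net mixing |

# Problem sizes used by the test suite

The suite validates recovery at 3,000 transcripts × 8 fractions × 3
replicates × 2 conditions (mean absolute proportion error below 0.05, over
90% of profiles passing QC), rank recovery on 120 × 8 matrices over 20
seeds, sign recovery of planted logistic effects at n = 2,000 with 50 noise
features over 20 seeds, and null calibration of the GAM comparison over 200
simulations of 150 observations — sizes chosen so the full suite exercises
every claim at desk scale.

# Known limitations

Proportions are marker-relative, not spatial coordinates; compartments not
separable on the gradient are invisible. The intercept filter assumes the
constant vector is not spanned by the marker basis — true for banded real
gradients, and enforced by the simulator's archetype design, but a
pathological basis would make $c$ unidentifiable. The outlier rule applied
literally removes both members of a discordant PSM pair. BANDLE-style
posterior probabilities are consumed, never computed. Manual curation
steps of the original marker sets are represented only as an auditable
blacklist mechanism.
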