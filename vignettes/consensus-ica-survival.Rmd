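---
title: "Consensus ICA of tumor transcriptomes: models, choices, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ICA of tumor transcriptomes: models, choices, and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cicasurv)
```

## The model

The pipeline treats a log-scale genes × samples expression matrix as a
linear mixture of a small number of statistically independent
transcriptional programs,

$$X \approx S\,M^\top,$$

where the columns of $S$ (genes × k) are *transcriptional components*
(TCs): gene-weight vectors whose entries give the direction and magnitude
of each gene's participation in one program. The rows of $M$ (samples × k)
are *activity scores*: how strongly each program is expressed in each
sample. Independence is imposed across genes — component weight vectors are
mutually independent, heavy-tailed random fields over the genome — which is
what lets ICA identify them where PCA only identifies a rotation-invariant
subspace. Biologically interpretable TCs in tumor compendia are leptokurtic:
a few hundred genes carry most of the weight (pathway programs), or a
contiguous genomic run carries same-sign weight (the downstream dosage
footprint of a copy-number alteration).

Everything downstream consumes this factorization: gene-set enrichment and
genomic footprint scans annotate the columns of $S$; Cox models,
permutation false-discovery selection and the survival tree consume columns
of $M$; cross-study and spatial projection re-estimates $M$ for new
profiles with $S$ held fixed.

## Centering, whitening and the data space

`center_genes()` removes each gene's mean across samples. `whiten()`
additionally removes each sample's mean across genes before the SVD. The
second step deserves a comment: activities are meant to reflect contrasts
*between genes*, not profile-wide shifts, and removing per-profile offsets
makes the retained singular vectors exactly orthogonal to the constant gene
vector. That in turn makes two conventions exact rather than approximate:
the TC columns have mean 0 and variance 1, and a noiseless mixture is
reconstructed with (numerically) zero residual. Projection
(`project()`) and reconstruction apply the same double-centering, so the
training data projects back onto the stored mixing matrix to machine
precision — a property the test suite asserts at `1e-6`.

Whitening retains `d` principal axes — by default the smallest number
reaching 90% cumulative variance, with `d` and `k` both overridable. The
source compendium in the original application retained several hundred
components from ~1100 samples without an explicit selection rule, so the
variance target is an explicit stand-in; for planted-truth simulations we
pass `k` equal to the planted rank and a `d` modestly above it (the
workflow uses `d = 2k`), which absorbs noise directions without starving
the rotation.

## FastICA and the consensus

`fastica_run()` is symmetric fixed-point FastICA with the `logcosh`
contrast (tolerance `1e-6`, at most 500 iterations) on the whitened
gene-observation representation, from a seeded random orthonormal start.
Runs that do not converge are flagged but kept: the consensus averages over
restarts, and discarding hard restarts would bias the consensus toward easy
components.

`consensus_components()` back-projects every run's sources to gene space
and clusters them greedily across runs by absolute Pearson correlation
(threshold 0.8), allowing at most one member per run per cluster. Clusters
present in at least half the runs survive; the consensus TC is the
standardized mean of sign-aligned members, and *credibility* is the mean
pairwise |r| within the cluster — 1.0 means every restart found the same
component. Sign is fixed by requiring the largest-|weight| gene to be
positive; ICA signs are otherwise arbitrary and tests need determinism.

## Projection

`project()` intersects genes, centers the new data within itself
(genes, then profiles), and solves ridge-stabilized (ε = 1e-8) normal
equations for each profile's activity vector. Two design points:

* Genes are *not* rescaled to unit SD by default. Rescaling interacts
  badly with leptokurtic weights — dividing a gene dominated by one
  component by its own SD compresses the weight information toward a sign
  vector — and would break the exact self-projection identity. For
  cross-platform use where per-gene scales are incomparable,
  `scale_genes = TRUE` applies the conventional unit-SD standardization.
* A single profile has no within-dataset baseline; in that case only the
  profile's own mean is removed.

`flag_outlier_activity()` applies the |activity| > 0.05 convention used to
call heightened-activity samples and cell lines.

## Gene-set enrichment

`enrichment_z()` is a competitive parametric (PAGE-style) statistic:
$Z = (\bar w_{set} - \bar w)\sqrt{m}/\mathrm{sd}(w)$ over the $m$ set
members present in the matrix, with a two-sided normal p and Bonferroni
correction over the collection. The reporting convention |Z| > 2 marks a
set as enriched. With heavy-tailed weights the normal reference is only
approximate in the far tail — a 10,000-draw random-set oracle in the test
suite bounds the discrepancy — and Bonferroni absorbs the residual
anti-conservatism; the type-I criterion is checked by simulation. Sets with
fewer than 3 usable members are flagged untestable rather than scored.

Note that the statistic is *directional*: it detects a signed mean shift.
The synthetic generator therefore plants enriched sets from a component's
top positive-weight genes; a set mixing a component's strongest positive
and negative genes is not enriched in this sense, however extreme its
absolute weights.

## CNA footprints

`detect_cna_regions()` orders each chromosome's genes by position, scans a
sliding window (30 genes) of mean signed weight, and calls windows whose
|mean| exceeds the $1-\alpha/n_{windows}$ quantile of a permutation null,
merging overlapping significant windows. The null shuffles gene order
within the chromosome: this breaks contiguity while preserving the weight
distribution, which is exactly the alternative/null contrast a dosage
footprint implies. A circular-shift null is also available
(`null = "circular"`) but is degenerate for this statistic — window means
are translation-equivariant, so circular shifts merely rotate the observed
window means and a strong block contaminates its own null; we default to
the permutation null for that reason. Chromosomes shorter than the window
are skipped with a warning.

## Survival association

`cox_fit()` is the reporting fit: `survival::coxph` (Efron ties) of OS on
the unit-SD-standardized activity plus any clinicopathological covariates,
yielding hazard ratios per activity SD.

The permutation machinery uses a different, deliberately cheaper statistic:
the Cox partial-likelihood *score* (log-rank-type) statistic
$U_j = \sum_i a_i z_{ij}$, where $a$ are the null-model martingale-type
weights and $z_j$ a component's activities. Because $\sum_i a_i = 0$, $U_j$
has exact permutation moments, and the whole permutations × components
p-matrix is a single matrix product — which is what makes 10,000
permutations × hundreds of components tractable. The observed p-values
entering the selection are computed with the same statistic, preserving
exchangeability between observed and null; `coxph` remains available for
effect-size reporting. With covariates, $a$ becomes the martingale
residuals of the covariate-only Cox model (an adjusted score test).
Permutations shuffle the outcome-plus-covariate rows jointly against the
activity rows, preserving the inter-TC correlation of the k statistics —
the sense in which the framework is "multivariate"; the identity
permutation is excluded from the null.

`multivariate_permutation_select()` controls the false-discovery
*proportion*: at candidate count $r$ with $u(r)=\lfloor\gamma r\rfloor$
tolerated false discoveries, the $r-u-1$ most significant components are
set aside and the $(u+1)$-th smallest observed p must fall below the
$(1-\text{confidence})$ quantile of the $(u+1)$-th order statistic over the
remaining columns' permutation p-vectors; selection stops at the first
failure. Under a global null this keeps the probability of any selection
near $1-\text{confidence}$. The default $\gamma$ is 1% at 80% confidence;
the 5% convention used in results-level reporting of the same framework is
available through the `gamma` argument.

## The survival tree

`best_split()` scans every classifier at every midpoint between
consecutive distinct values, scoring each candidate with the two-group
log-rank statistic; candidates leaving a child under 17 patients are
inadmissible, and ties on p break by larger chi-square, then classifier
name, then smaller cutoff — all deterministic. `grow_tree()` recurses
depth-first and stops a node when it has fewer than 50 patients, fewer
than 25 events, or no admissible split; leaves are labelled left-to-right.
No multiplicity adjustment is applied across candidate cutoffs inside the
tree (the selection is by raw log-rank p), a known optimism source that the
subsample robustness statistic is meant to expose.

Three caveats that simulation makes concrete:

* *Cutoff resolution.* The maximally selected log-rank cutoff localizes a
  planted threshold only to within roughly ±10 observations at these
  cohort sizes when the classifier is continuous. The planted-threshold
  recovery experiment therefore uses an ordinal classifier (20 levels,
  ~15 patients per level), matching the ordinal clinicopathological
  classifiers the tree consumes; at that resolution the optimal cutoff is
  identified at the level boundary.
* *Robustness is overlap-biased.* `tree_robustness()` Spearman-correlates
  the per-classifier root-split p-ranking of each 80% subsample with the
  full-cohort ranking. An 80% subsample shares most of its patients with
  the cohort, so even pure-noise classifiers produce positive rank
  correlations; the statistic measures the stability of *this cohort's*
  ranking, not significance against a noise null. The per-iteration top
  classifier is also returned, which is the sharper diagnostic.
* *Concordance ties.* `tree_concordance()` ranks leaves by Kaplan–Meier
  median OS and uses the (negated) rank as the risk score. Comparable
  pairs within one leaf are risk-tied and count 1/2 under the standard
  Harrell convention, so C cannot reach 1 for any leaf-grouped risk score;
  the attainable maximum depends on leaf sizes. The standard error is the
  Noether binomial-type estimate over comparable pairs.

## Spatial maps and colocalization

`spot_pvalues()` projects the TCs onto library-size-normalized
(`normalize_counts()`, 10,000 counts then `log1p`) spot profiles and builds
a per-(TC, spot) null by shuffling the gene-to-weight assignment within
each TC column and re-projecting — 3000 permutations by default (the
figure-level convention of 5000 is a parameter away). The permuted object
is the weight assignment rather than the spot profile: this preserves each
spot's expression profile and each TC's weight distribution exactly, and
asks precisely whether the *alignment* of weights to genes explains the
activity. Two-sided p-values use the add-one estimator (never 0) and map to
signed z-scores $\mathrm{sign}(a)\,|\Phi^{-1}(p/2)|$.

`colocalization()` thresholds two signed z maps at |z| > 1.96 into positive
and negative active regions and combines Jaccard overlaps:
$2[J(A^+,B^+)+J(A^-,B^-)] - 2[J(A^+,B^-)+J(A^-,B^+)]$, with $J = 0$ for an
empty side. The score is symmetric and bounded in $[-4, 4]$: +4 when both
signed regions coincide, −4 under exact sign inversion, 0 when the active
regions are disjoint. The 1.96 region threshold is the conventional
two-sided 5% cut and is configurable. Note that with two complementary
tissue regions and within-dataset centering, a component confined to one
region is necessarily "down" in the other, so strongly negative scores
between components of complementary regions are expected geometry, not an
artifact.

## The synthetic generator

`make_sources()` plants unit-variance components that are either sparse
Laplace fields (default 2.5% non-zero, scale 3 before standardization —
planted zeros stay exactly zero) or CNA-like contiguous same-sign runs of
30–80 genes on one chromosome; columns are re-drawn until pairwise |r| <
0.2. `make_mixing()` draws standardized Gaussian activities (requiring
n ≥ 3k for identifiability). `make_expression()` adds i.i.d. Gaussian noise
(default SD 0.2 against unit-variance signal). `make_clinical()` generates
exponential event times under a proportional-hazards model on selected
activities plus age ((age−60)/10) and stage (stage−3) at a baseline of
1/60 per month, with independent exponential censoring (default 1/120);
`make_spatial()` gives regions of a spot grid planted activity 2.0 and
draws Poisson counts from a softplus-linked intensity at ~2000–4000 counts
per spot; `make_gene_sets()` plants directional enrichment as described
above. Every generator is deterministic given its seed.

What the generator does **not** emulate — and hence what green tests do not
certify on real data: microarray probe effects and batch structure, tumor
purity and stromal admixture, non-proportional hazards and informative
censoring, spatial spot-to-spot correlation beyond region membership, and
platform differences between the training compendium and projection
targets (the `scale_genes` option exists for the latter).

## Numerical conventions and problem sizes

Ridge ε = 1e-8 in all projection normal equations; FastICA tolerance 1e-6;
consensus match threshold 0.8 with ≥50% run occupancy; enrichment requires
≥3 usable members; CNA scan defaults to 30-gene windows, 1000 permutations,
α = 0.01 Bonferroni-corrected over windows; permutation FDP defaults to
10,000 permutations, γ = 0.01, confidence 0.8; tree thresholds 50/25/17;
spatial maps default to 3000 permutations and a 1.96 region threshold.
Gene-id ties in rankings break lexicographically. Genomic coordinates are
1-based inclusive; only within-chromosome order is consumed.

The test suite exercises the pipeline at the sizes the methods assume while
staying desk-sized: decompositions of 2000 genes × 300 samples with k = 10
and 25 runs; survival calibration with 200 components at n = 300 over 1000
permutations and 200 replicates; tree recovery over 100 replicates at
n = 300; spatial calibration with 500 null spots at 500 permutations. The
`analysis/` scripts run the same machinery end-to-end on one simulated
cohort and write their tables under `results/`.

## Known limitations

The consensus clustering is greedy reference matching, not a full pairwise
graph clustering; with well-separated components the two coincide, under
heavy noise the greedy pass can split a cluster. The enrichment normal
reference is anti-conservative in the extreme tail for very heavy-tailed
weight columns. The adjusted permutation score test residualizes only the
outcome side; covariates strongly correlated with an activity will reduce
its power rather than bias it. Survival-tree p-values are selection-biased
by construction and should be read as ranking scores, not calibrated
significance levels.
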