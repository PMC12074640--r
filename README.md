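# cicasurv

Bulk tumor transcriptomes are weighted sums of transcriptional programs —
proliferation, immune infiltration, stromal content, the dosage footprints
of copy-number alterations — and no clustering of whole samples can see
these programs separately. `cicasurv` implements the alternative: consensus
independent component analysis (c-ICA) decomposes a genes × samples
log-expression matrix as

    X ≈ S Mᵀ

into statistically independent **transcriptional components** (TCs; columns
of `S`, gene-weight vectors) and their per-sample **activity scores**
(rows of `M`), and then carries those components through the full analysis
a tumor-compendium study needs:

* **Decomposition** — whitening, many randomized FastICA (logcosh) runs,
  cross-run clustering into consensus TCs with a per-TC credibility index
  (`consensus_ica()`).
* **Annotation** — competitive gene-set enrichment Z-scores with Bonferroni
  correction (`enrichment_z()`), detection of contiguous genomic weight
  blocks that mark CNA-driven components (`detect_cna_regions()`),
  co-functionality clusters among a TC's top genes
  (`cofunctionality_clusters()`), prominent-gene lookup
  (`prominent_gene_tcs()`).
* **Survival** — Cox models of overall survival on TC activities
  (`cox_fit()`), a multivariate permutation framework that controls the
  false-discovery proportion at a stated confidence
  (`select_survival_tcs()`), and a log-rank recursive-partitioning survival
  tree with subsample robustness and Harrell's concordance
  (`grow_tree()`, `tree_robustness()`, `tree_concordance()`).
* **Projection** — fixed TCs projected onto new bulk, cell-line or spatial
  profiles (`project()`), permutation significance maps over Visium-like
  spots (`spot_pvalues()`), and pairwise colocalization scores in [−4, 4]
  (`colocalization()`).
* **Synthetic data** — generators that plant sparse leptokurtic sources,
  CNA blocks, proportional-hazards survival effects, enriched gene sets and
  spatially confined components (`make_sources()` and friends), so every
  stage has a ground-truth recovery test.

The intended user is a computational biologist analyzing a microarray or
RNA-seq compendium (the design target was ovarian-cancer transcriptomes)
who wants component-level biology, survival-associated programs, and
spatial localization of those programs, with every statistical step
testable against planted truth.

## Worked example

The `analysis/` scripts run the whole pipeline on one simulated cohort
(2000 genes × 300 samples, 10 planted components of which 2 are CNA-like,
3 driving survival, 2 confined to spatial regions):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_decompose.R
Rscript analysis/03_annotate.R
Rscript analysis/04_survival.R
Rscript analysis/05_tree.R
Rscript analysis/06_spatial.R
```

Output (abridged) and what it means:

```
consensus ICA: 10 TCs from 25 runs (25 converged)
  credibility: median 1.000 (min 1.000)
planted-source recovery (|r| with best-matching consensus TC):
 src1  src2  src3  src4  src5  src6  src7  src8  src9 src10
0.999 0.998 1.000 0.999 1.000 0.999 1.000 0.999 1.000 1.000
```

Every planted source is recovered by a consensus TC at |r| ≥ 0.998, and
credibility 1.0 says all 25 restarts found the same components.

```
CNA scan: 2 of 10 TCs carry a genomic footprint (2 planted)
univariate: 3 TCs selected at FDP <= 1%, confidence 80%: TC8, TC4, TC2
 tc_id    hr     se        p
   TC8 0.504 0.0808 2.13e-17
   TC4 1.678 0.0768 1.63e-11
   TC2 0.666 0.0804 4.45e-07
```

The permutation selection finds exactly the three TCs matching the planted
survival effects (hazard ratios per activity SD; the planted effects were
protective for two components and harmful for one).

```
concordance of leaf risk ordering: C = 0.765 (SE 0.002, 31271 pairs)
  src1 (planted in region 1) -> TC8: Jaccard(sig+, region) = 1.00
  src3 (planted in region 2) -> TC2: Jaccard(sig+, region) = 1.00
colocalization between the two regional TCs: -4.00
```

The survival tree's leaves order patient risk (C = 0.77); the spatial
significance maps recover both planted tissue regions exactly, and the two
components confined to complementary regions score −4 (perfect inverse
colocalization — where one is up the other is down).

Intermediate matrices land under `scratch/`, small result tables under
`results/`.

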