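# scStageNet

Keratinocytes renew the epidermis by moving from a proliferative basal
state (BK) through a mitotic transition into the differentiated state (DK)
that builds the skin barrier. Which transcription factors (TFs) drive that
switch, and which gene programs they control, can be read out of single-cell
RNA-seq when it is combined with regulatory evidence from state-specific
super-enhancers (SEs). scStageNet implements that analysis as a tested,
self-contained R package for computational biologists who want to run,
probe, or extend the pipeline without controlled-access data: a bundled
synthetic-data generator produces every input with planted ground truth.

The pipeline:

* **Staging.** Cells are normalized (`log2(cpm + 1)`), embedded by PCA,
  smoothed by MAGIC-style diffusion imputation over an adaptive-kernel kNN
  Markov operator, and partitioned into K = 8 stages by k-means-based
  approximate spectral clustering; within-stage outliers are removed and
  expression re-imputed at reduced diffusion time.
* **Specificity screen.** A CAGE-style bulk atlas is screened per gene with
  Mann-Whitney U tests (target cell type vs all others; BH FDR < 0.05 and
  elevated mean), filtered on single-cell expression (>= 1 UMI in >= 1% of
  cells), and assembled into the TF/gene analysis sets.
* **Moderated DE.** A reimplemented two-group limma-trend-style test
  contrasts BK (stages 1-3) with DK (stages 5-7); genes at FDR < 0.05 with
  |moderated log2 FC| > 0.25 are state-specific.
* **Trajectories.** Stage-wise mean imputed profiles are filtered for
  dynamic range and clustered by Pearson correlation distance; the two TF
  branches separate basal-peaking from differentiation-peaking regulators,
  and the basal-peaking antioxidant cluster size gets an exact binomial
  test.
* **SE motif enrichment.** PWMs are scanned (exact integer-score null,
  p <= 1e-4, both strands) over both SE sets; per-kb counts are compared
  between states (Mann-Whitney, BH), giving each TF a direction and a
  rank-biserial magnitude `2*AUC - 1`; a one-sided test checks concordance
  between expression branches and enrichment directions.
* **Module networks.** Signed soft-thresholded similarity
  `s_ij = sign(r_ij)|r_ij|^beta` (beta = 6) between state-enriched TFs and
  candidate targets over the state's stage window is clustered into TF and
  gene modules; module pairs with `|mean s|` above a permutation-calibrated
  threshold become signed activation/inhibition edges.
* **Prioritization.** Candidate TFs are scored by
  `sum(sign(r) * log2FC(DK-BK))` over their correlated targets; strongly
  negative scores nominate basal-state promoters, filtered at >= 5 FPKM in
  undifferentiated culture.

## Worked example

```r
library(scStageNet)
res <- run_pipeline(simulation_config(seed = 1))
```

The run logs each stage with the sizes surviving its filters:

```
simulate: 1500 genes x 3000 cells, 15 motifs
orientation: basal-enriched TFs peak late; reversing stage axis
stage: 8 stages, 2819/3000 cells retained after outlier removal
specificity: 361 screen hits, 361 keratinocyte genes, 10 keratinocyte TFs
de: 608 BK-specific, 804 DK-specific of 1500
trajectories: 10 dynamic TFs in 2 branches; 32 dynamic antioxidant genes
motifs: 5 BK-enriched, 5 DK-enriched of 15; concordance p = 0.00397
network: BK 8 edges; DK 7 edges
prioritize: 10 ranked candidates; top = TF03
```

The motif table assigns every planted basal TF a basal direction with a
positive signed magnitude (and the mirror image for differentiated TFs),
null motifs stay unassigned, and the branch/enrichment concordance test
gives p = 0.00397:

```r
subset(res$enrichment$table, direction != "none")
#>      tf        q direction signed_magnitude
#> 1  TF01 7.03e-09        BK            0.694
#> 2  TF02 1.33e-07        BK            0.621
#> ...
#> 10 TF10 2.16e-10        DK           -0.769
```

The most negative differentiation-promoting scores — the predicted
basal-state promoters nominated for knockdown — are the planted basal TFs:

```r
head(res$ranking[, c("tf", "score", "n_targets")], 3)
#>     tf  score n_targets
#> 1 TF03 -555.2       258
#> 2 TF02 -537.8       269
#> 3 TF04 -518.8       245
```

And the antioxidant panel shows its basal-state preference: 20 of 32
dynamic antioxidant genes fall in the basal-peaking cluster (exact
binomial p = 0.000687).

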