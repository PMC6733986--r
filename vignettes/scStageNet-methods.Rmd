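---
title: "Staging keratinocyte differentiation and building module-level regulatory networks"
author: "scStageNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging keratinocyte differentiation and building module-level regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Epidermal keratinocytes move through a differentiation program: basal
(progenitor) cells (BK) divide against the basement membrane, pass through a
mitotic transition, and mature into differentiated keratinocytes (DK) that
build the cornified barrier. scStageNet reconstructs this program from
single-cell RNA-seq and couples it to regulatory evidence from
super-enhancers (SEs):

1. **Staging** — cells are ordered into K discrete stages (default 8: basal
   stages 1–3, a mitotic-like stage 4, differentiated stages 5–7, and an
   off-trajectory "channel"-like stage 8) by diffusion imputation followed by
   k-means-based approximate spectral clustering.
2. **Specificity screen** — a bulk cell-type atlas (CAGE-style) is screened
   with per-gene Mann-Whitney U tests for genes and transcription factors
   (TFs) specifically elevated in the target cell type, filtered by minimum
   single-cell expression, and assembled into the analysis gene sets.
3. **Differential expression** — a reimplemented two-group limma-trend-style
   moderated test contrasts the BK (stages 1–3) and DK (stages 5–7) cell
   unions on `log2(cpm + 1)` of non-imputed counts; genes with FDR < 0.05 and
   |moderated log2 FC| > 0.25 are called state-specific.
4. **Trajectory clustering** — stage-wise mean imputed expression profiles
   are filtered for dynamic range and clustered with Pearson correlation
   distance (average linkage); the two main TF branches separate
   basal-peaking from differentiation-peaking regulators, and an antioxidant
   gene panel is clustered the same way with an exact binomial test for the
   size of its basal-peaking cluster.
5. **SE motif enrichment** — TF motifs are scanned over the two state-labelled
   SE sequence sets; length-scaled occurrence counts are compared between
   states per motif (Mann-Whitney U, BH across motifs), each significant TF
   receives a direction and a rank-biserial signed magnitude, and a one-sided
   test asks whether the expression branches agree with the enrichment
   directions.
6. **Module networks** — per state, a signed soft-thresholded similarity
   `s_ij = sign(r_ij) |r_ij|^beta` between enriched TFs and candidate target
   genes over the state's stage window (BK: stages 1–4; DK: stages 4–7) is
   clustered into TF modules (expression similarity) and gene modules
   (similarity of TF-correlation profiles); module pairs whose mean signed
   similarity exceeds a calibrated threshold become signed regulatory edges.
7. **Prioritization** — candidate TFs are scored by the sum of
   `sign(r) * log2FC(DK - BK)` over their correlated targets; strongly
   negative scores nominate basal-state promoters, filtered by culture
   expression (FPKM >= 5) before ranking.

```{r}
library(scStageNet)
res <- run_pipeline(simulation_config(seed = 1))
```

# The staging model and its assumptions

Raw UMI counts are normalized to `log2(cpm + 1)` and embedded with PCA
(default 30 components). A cell-cell Markov diffusion operator is built on
that embedding from an adaptive Gaussian kernel (`k_neighbors = 30`,
bandwidth at the `ka_adaptive = 10`-th neighbor), symmetrized and
row-normalized. Counts-per-million are imputed by `t` steps of diffusion
averaging; the embedding of the imputed expression is then clustered.

The approximate spectral clustering summarizes cells by `m_representatives`
k-means centers (default 800), builds a Gaussian affinity among centers with
the median pairwise distance as bandwidth, takes the top-K eigenvectors of
the symmetric normalized adjacency, row-normalizes them, k-means-partitions
that spectral embedding into K clusters, and lets each cell inherit its
center's cluster. With `m_representatives >= n` the procedure reduces
exactly to plain normalized spectral clustering, which the test suite
verifies. Disconnected center graphs (kernel underflow between very distant
groups) are clustered per component with a warning.

Stage labels are ordered by the cluster means along the first principal
axis. The sign of a principal axis is arbitrary, so the pipeline orients the
axis with the only external information that declares which end is basal:
the state labels of the SE sets. TFs whose motifs are enriched in the
basal-labelled SE set must peak early; if they peak late, the stage numbering
is reversed. This mirrors marker-based stage identification while using only
declared inputs, and it is deterministic.

After staging, within-stage outliers (distance to the stage centroid above
`median + c * MAD`, default `c = 3`, strict inequality) are removed to
reduce false-positive correlations, and expression is re-imputed at a
**reduced** diffusion time for all downstream correlation analysis.

**Choice of re-imputation time.** The default is `t_reimpute = 1` (first
pass: `t_impute = 6`). At larger times the diffusion average approaches the
stage means, so any two genes aligned with the differentiation axis
correlate near ±1 and TF-target structure becomes indistinguishable from
generic trend correlation; one step suppresses sampling noise while
preserving the cell-level variation that correlation-based target calling
needs. Both times are parameters of `pipeline_params()`.

# Statistical components

* **Mann-Whitney U** (shared by the screen, the motif comparison, and the
  concordance test): midranks for ties; exact enumeration of all rank
  assignments when the pooled sample size is at most 12 and untied,
  otherwise a tie-corrected normal approximation with continuity correction.
  The switch point is fixed so results are bit-for-bit reproducible.
* **Benjamini-Hochberg** q-values by the textbook step-up rule.
* **Moderated DE**: per-gene pooled two-sample variances are squeezed toward
  an empirical-Bayes prior estimated by moment-matching the log sample
  variances (digamma/trigamma equations; the prior degrees of freedom by
  Newton inversion of the trigamma function). With `trend = TRUE` the prior
  scale follows a lowess fit of the log variances against mean
  log-expression. Degenerate cases: near-constant log variances give an
  infinite prior (pooled variance, with a warning); a forced prior of zero
  degrees of freedom recovers the ordinary t-test exactly.
* **Motif scanning**: integer-rounded (two decimal digits of log2 odds)
  position weight matrix scores on both strands; the hit threshold is the
  smallest score whose exact per-position null p-value — computed by dynamic
  programming over the integer score distribution under the background — is
  at most `scan_p` (default 1e-4). Overlapping hits all count; N bases
  contribute zero log-odds. Counts are scaled to occurrences per kilobase of
  region length.
* **Enrichment magnitude**: the rank-biserial effect `2*AUC - 1` attached to
  the Mann-Whitney comparison, signed positive toward the basal SE set. It
  is bounded, sign-symmetric, and consistent with the test used.
* **Cluster-size enrichment**: exact binomial upper tail at the
  equal-probability null `1/n_clusters`, by direct summation.
* **Set enrichment**: a generic hypergeometric upper-tail utility with BH
  correction stands in for web-service ontology queries.

# Module networks

Within a state's stage window, the TF side is the set of TFs with motifs
enriched in that state's SEs; the gene side is the keratinocyte gene set
minus genes specific to the *other* state (a BK network excludes
DK-specific genes and vice versa) — the test suite verifies that manual
pre-filtering gives the identical network. Zero-variance rows over the
window are dropped with a message.

The soft-threshold power defaults to `beta = 6`, the conventional value for
signed coexpression networks; `beta = 1` returns the raw correlation matrix
exactly. TF modules default to one per TF (the planted regulators are
independent latent factors; on real data a smaller count merges co-acting
TFs and is exposed as `n_tf_modules`). Gene modules default to five per TF
plus one: activating and repressed targets of one TF anticorrelate and land
in separate modules, and the surplus modules give weakly attached genes
somewhere to go without diluting coherent blocks. Module counts are
data-dependent choices, not constants of nature; both are parameters.

Edges are called on the block means of the signed similarity over all
(TF module, gene module) pairs. The default threshold is the 95th
percentile of a permutation null (gene-module labels shuffled, block means
pooled over at least 100 permutations). An alternative rule,
`edge_threshold_bimodal()`, splits the observed block-mean distribution
above the permutation floor at the exact two-class minimum-variance (Otsu)
cut; it is stricter and trades recall for precision.

# Prioritization

Targets of a candidate TF are genes whose |Pearson r| with the TF over the
on-trajectory stages (1..K-1) of the re-imputed log expression reaches
`min_abs_r` (default 0.3; raw, not soft-thresholded, so the score keeps
interpretable units). The differentiation-promoting score sums
`sign(r) * log2FC(DK - BK)` over those targets, so a TF that activates
basal genes and represses differentiation genes scores strongly negative.
The audit list of targets is stored with each score and reproduces it
exactly. Candidates below 5 FPKM in undifferentiated culture are excluded
(strict inequality: exactly 5 is kept); the synthetic pipeline derives the
culture table from basal-stage expression.

# What the synthetic-data generator emulates

`simulation_config()` defaults describe the study conditions: 3,000 cells
and 1,500 genes over 8 stages; 10 keratinocyte TFs (5 basal, 5
differentiated) with 20 signed targets each (70% activating); 150
additional cell-type-specific genes; a 32-gene antioxidant panel in three
classes (20 basal-peaking, 6 mid, 6 late); a 495-sample bulk atlas with a
3-sample target group elevated by 4 log2 units; 50 SE regions per state
(1–3 kb) with motif consensus sites planted as a Poisson process at 0.5
occurrences/kb, tripled in each motif's enriched state, plus 5 unenriched
null motifs.

Mechanistically, every gene carries a smooth unimodal log2 stage
trajectory; a marker-like minority (45% of ordinary genes) has sharp,
strong trajectories (3.5–5.5 log2 amplitude), which is what gives the
discrete stages their separation, as strongly stage-restricted markers do
in real epidermis. Each TF's latent activity is its stage bump (staggered
peak positions; amplitude 1.5–2.2) plus per-cell Gaussian noise
(`latent_noise_sd = 0.8` log2 units); targets track the centered latent
with coupling 1.5 and the planted sign, plus their own noise at half that
standard deviation. The cell-level activity variation is deliberately
substantial: it is the information that correlation-based target calling
uses, and it must rival the within-window trajectory overlap of same-state
TFs or their regulons would be statistically inseparable. Counts are
negative binomial (dispersion 0.1) around library-size-scaled means
(lognormal library sizes, mean 5,000 UMIs, CV 0.3) with 30% independent
dropout. All randomness flows from one root seed through named substreams,
so partial reruns reproduce exactly.

Deliberately **not** emulated: batch effects, doublets, ambient RNA,
continuous pseudotime within stages (stages are discrete for unambiguous
truth labels), genome-derived sequence composition, and chromatin signal
tracks. Passing tests therefore show that the implementation recovers the
structure this model plants under realistic count noise — not that it is
robust to artifacts the model omits.

# Numerical choices and degenerate inputs

* Zero-variance genes z-score to all-zero rows and are flagged, never NaN.
* All-zero cells are a named error in `normalize_log_cpm()`.
* Duplicate embedding points with zero adaptive bandwidth fall back to the
  global median distance.
* Ties in peak-stage calls resolve to the lowest stage and are flagged.
* Hierarchical clustering sorts identifiers lexicographically first, making
  tie-breaking deterministic in the ids rather than the input order.
* Constant gene profiles in module clustering are assigned to the nearest
  module centroid by Euclidean distance and flagged.
* The Mann-Whitney exact/approximate switch is fixed at pooled n = 12.
* Integer seeds derived from the root seed stay below 2^31.

# Problem sizes used by the checks

The bundled tests and the acceptance script run the full pipeline at the
default 3,000-cell configuration once, plus oracle suites on small
instances (exact Mann-Whitney enumeration up to pooled n = 10, exhaustive
PWM window scoring up to 50 bp, dense diffusion-operator construction at
n = 200, approximate-versus-exact spectral clustering at m = n), a 10,000
replicate Mann-Whitney null, a 2,000-gene moderated-DE null, and 100
reduced-size (500 cells, 300 genes) scoring replicates for the
prioritization ranking.

# Known limitations

* The module-edge threshold is calibrated, not derived; on data whose block
  means are not bimodal the permutation quantile is the safer default.
* Pair-level recovery of the planted regulome from module-level edges
  varies a few percent across simulation seeds; the residual errors are
  opposite-state targets that legitimately survive the DE filter and align
  with the window trend.
* The two-group moderated DE handles exactly the BK/DK contrast, not
  arbitrary design matrices.
* The stage-axis orientation rule needs at least one significantly enriched
  motif per state; without any, the ordering along the principal axis is
  reported as-is.
* Correlations on cpm-normalized values carry a compositional (closure)
  component; target identification therefore operates on imputed
  expression, and the generator's planted-sign invariant is stated on the
  count scale.
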