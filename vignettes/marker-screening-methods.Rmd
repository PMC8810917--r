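---
title: "Correlation-cascade screening for developmental surface markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-cascade screening for developmental surface markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimarker)
library(dplyr)
```

## The problem

The fetal ("active") epicardium is a transient progenitor tissue: its cells
express the transcription factors WT1 and TBX18 and the retinoic-acid enzyme
ALDH1A2, undergo epithelial-to-mesenchymal transition, and give rise to
smooth muscle cells and cardiac fibroblasts. The adult epicardium is
quiescent and this program is shut off. Because the defining genes are
transcription factors, they are useless for labelling or sorting live cells;
what is wanted is a **cell-surface** marker whose expression tracks the
active state and disappears in the adult tissue.

`epimarker` implements, as a reusable and testable pipeline, an in-silico
strategy for finding such markers in staged bulk RNA-seq data: a cascade of
correlation and expression filters anchored on the known state-defining
genes, a nonparametric differential-expression statistic, an
upstream-regulator prioritization by promoter motif scanning, and standard
sample-structure analyses. A synthetic-data generator with planted ground
truth makes every stage verifiable without any external download.

## The screening cascade

Given a gene-by-sample expression table, a stage design (ordered stages
`early < late < adult` with replicates), and a per-gene annotation
(surfaceome membership, transcription-factor membership), `run_screen()`
applies, in fixed order:

1. **Anchor correlation** — keep genes with Pearson `r >= r_anchor`
   (default 0.6) against *every* epicardial anchor (WT1, TBX18, ALDH1A2 by
   default). The threshold is applied to signed `r` because the anchors rise
   together across the early-to-late axis; an absolute-value mode
   (`absolute_r = TRUE`) is available.
2. **Surfaceome filter** — intersect with the user-supplied surface flag.
   The surface list is deliberately an input: surfaceome catalogues differ
   and the screen should not hard-code one.
3. **Differential expression** — keep genes called differentially expressed
   between the early and late stages by the (M, D) statistic below.
4. **Endothelial exclusion** — keep genes with a *significant negative*
   correlation (`r < 0` and two-sided `p < alpha`, default 0.05) to every
   endothelial anchor (CDH5, PECAM1 by default). This removes genes that
   track contaminating endothelial lineages. "Significant" is fixed as the
   standard t-test on a correlation coefficient,
   `t = r * sqrt(n-2) / sqrt(1-r^2)` with `n - 2` degrees of freedom,
   because no cutoff is otherwise implied by a heatmap colour scale.
5. **Fold-change top-k** — rank surviving genes by `log2` fold change of
   late over early stage means (pseudocount 1 on the normalized scale) and
   keep the top `top_k`. The default is 3 — a shortlist small enough to
   validate experimentally; recovery experiments over ten planted markers
   use `top_k = 10` so that sensitivity is measurable over all of them.
   Ties are broken lexicographically by gene id so results are
   deterministic.
6. **Confirmation correlation** — re-apply the anchor threshold
   (`r_confirm`, default 0.6) to the ranked shortlist.
7. **Adult exclusion** — require
   `mean_adult / (mean_late + c) <= adult_max_fraction` (default 0.05).
   "Not expressed in adult tissue" is inherently qualitative; 5% of the
   late-stage level is adopted as a quantitative reading and is
   configurable.

Every gene keeps a complete ledger row (all stage flags and statistics),
survivor sets are nested by construction, and the result is invariant to
row and column permutations of the input.

Correlations are computed on `log2(cpm + 1)`; fold changes and the DE
statistic on the cpm scale. The source analyses do not state their scale;
log-scale correlation is the common practice and both scales are exposed
through `normalize_expression()` / `log_transform()`.

## The nonparametric (M, D) differential-expression statistic

For conditions A and B, each gene gets `M = log2((mean_B + c)/(mean_A + c))`
and `D = |mean_B - mean_A|`. The null is empirical: for every unordered
same-condition replicate pair and every gene, the pair
`(|log2((x_i + c)/(x_j + c))|, |x_i - x_j|)` joins a noise pool. The DE
probability is the fraction of pool pairs strictly dominated by the gene's
`(|M|, D)`, and a gene is flagged when `prob > q` (default 0.8). This is the replicate-based variant of the
empirical noise-distribution approach to RNA-seq differential expression:
the simplest faithful construction of an (M, D)-versus-noise probability,
with the threshold left configurable.

Properties guaranteed and tested: `prob` is monotone in `|M|` and `D`;
records are invariant to within-condition sample permutation; global
rescaling leaves `M` and `prob` unchanged. Under a null where both
conditions are drawn from one distribution (4+4 replicates, 2000 genes) the
flagged fraction at `q = 0.8` averages well below 0.05.

One caveat is intrinsic to a *global* noise pool: dominance is ranked across
expression strata, so strongly-shifted low-count genes can rank below noisy
high-count genes when baselines are very heterogeneous. The power
experiment (ten-fold shifts on 50 genes all ranking on top) is therefore
defined over exchangeable genes — one shared baseline — which is the only
setting in which the property is well-posed. Conditions without replicates
are rejected with an explicit error rather than silently approximated.

## Upstream-regulator prioritization

Starting from a candidate marker, `correlated_deg_set()` collects genes with
`r >= 0.6` to the candidate that are also DE between early and late stages;
`tf_intersection()` keeps annotated transcription factors; and
`prioritize_tfs()` ranks them by their best promoter binding score.

Motifs are JASPAR-format position frequency matrices turned into log-odds
weights: `w = log2(((n + p*b) / (N + p)) / b)` with pseudocount `p`
(default 1, distributed by background `b`, default uniform). Every window on
both strands is scored; windows containing `N` are skipped; minus-strand
hits are reported in plus-strand coordinates (0-based, half-open). Scores
are min-max normalized to a **relative score** in [0, 1] — the convention
behind "relative binding score" in JASPAR-style tools — so the consensus
scores exactly 1.0. The default reporting threshold is 0.80. Promoter
sequences are supplied as-is; the generator's default is 1000 bases ending
at the transcription start site, since regulator binding is expected near
the TSS.

The bundled `gata_like_pfm()` is a **synthetic** WGATAA-core motif written
for simulation and testing; it is not a database matrix.

## Sample-structure analyses

* `pca_samples()` — samples as observations, genes centered (optionally
  scaled), deterministic sign convention (largest-magnitude loading
  positive per component). Variance-explained fractions are reported per
  component and sum to 1. When stages separate on PC1, the PC1 fraction is
  the natural reading of "variance between" two stage groups; that
  interpretation is reported, not asserted.
* `manhattan_distances()` + `agnes_cluster()` — bottom-up agglomeration
  with Lance-Williams updates (average, single, complete linkage). The
  nearest-pair tie is broken by the smallest index pair, which `hclust`
  does not guarantee, so merge histories are reproducible; `hclust` is used
  as an independent cross-check in the tests. Trees export to Newick with
  leaves at depth equal to their final merge height.
* `kmeans_samples()` — seeded Lloyd iterations, best of `n_init` restarts.

## The synthetic-data generator

`simulate_expression()` emulates a three-stage epicardial development
design: early and late active epicardium and adult quiescent tissue,
default 4 replicates each.

* **Anchors** follow a log2-scale trajectory with per-stage count means
  `early = 50, late = 500, adult = 5` — monotone rise and adult silencing at
  1% of the late level (the source states silencing only qualitatively).
* **Planted markers** share the anchors' latent per-sample trajectory plus
  independent Gaussian log2 noise whose variance is solved in closed form
  from the target Pearson correlation (default 0.9):
  `var_m = V^2 / (rho^2 (V + v_a)) - V`, where `V` is the trajectory
  variance and `v_a` the anchors' total noise. Because counts are sampled
  *downstream* of the latent trajectory, the count-noise contribution on
  the `log2(cpm + 1)` scale is measured by a short Monte-Carlo at each
  stage mean and included in `v_a` and subtracted from `var_m`; a pure
  delta-method term underestimates it badly at the low adult means, where
  occasional zero counts fall far below the trajectory after the log.
  Empirical correlations at 50 replicates per stage land within a few
  hundredths of the target.
* **Endothelial genes** follow the reflected trajectory (anti-correlated);
  **background genes** have i.i.d. per-gene baselines
  (`log2 mean ~ N(6, 1.5^2)`) and no structure; a configurable fraction of
  them is flagged surface (5%) and TF (1%) to supply decoys. Optional
  **adult-persistent** controls match the anchors early/late but stay high
  in adult samples.
* **Counts** are gamma-Poisson (variance `mu + phi mu^2`, default
  `phi = 0.05`) with per-sample log-normal library factors (CV 0.1) —
  standard bulk RNA-seq noise; the source gives no generative model.
* **Seeding**: one master seed fans out to named sub-streams per component
  (library sizes, each gene block, annotation flags, promoters), so adding
  genes of one class does not perturb the others and identical
  configurations are byte-identical on disk.

What the generator does **not** emulate: batch effects, isoform structure,
single-cell sampling, and the noise profile of any particular real
dataset. Passing tests demonstrate correctness of the pipeline's logic under
a plausible bulk RNA-seq model, not performance on any particular real
dataset.

## Problem sizes and numerical choices

Recovery and calibration experiments run at 2000 background genes, 10
planted markers, 3 stages x 4 replicates, averaged over 10 seeds; the
correlation-calibration check uses 50 replicates per stage over 20 seeds;
scanner and clustering equivalence checks use 100 and 50 random instances.
These sizes make every property estimate stable while keeping a full run in
minutes on a laptop.

Degenerate inputs are errors, not guesses: constant genes cannot enter
correlation filters (they are excluded with a warning), all-zero columns
cannot be cpm-normalized, replicate-free DE is refused, zero-variance PCA is
refused. Relative motif scores are clamped to [0, 1] to absorb last-bit
floating-point underflow at the score minimum. Fold changes and DE ratios
share one pseudocount (default 1 on the normalized scale).

## Limitations

The screen is a deterministic filter cascade, not an inferential procedure:
no multiplicity correction is applied across genes, and the thresholds
(`r >= 0.6`, `q > 0.8`, adult fraction 0.05) are design choices, exposed
in the configuration rather than asserted as optimal.
The (M, D) statistic ranks across expression strata (see above). The PWM
scanner assumes independent positions and a fixed background; it does not
model chromatin, conservation, or cooperative binding. Real surfaceome
annotations are incomplete and the screen is only as good as that input
list.
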