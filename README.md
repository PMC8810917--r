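# epimarker

Correlation-cascade discovery of developmental cell-surface markers in
staged bulk RNA-seq.

## The problem

The fetal ("active") epicardium — the mesothelial layer covering the
developing heart — is defined by transcription factors (WT1, TBX18,
ALDH1A2) that are useless for labelling or sorting live cells. A practical
marker must sit on the cell surface, track the active developmental state,
and switch off in the quiescent adult tissue. `epimarker` implements an
in-silico strategy for finding such markers from a staged expression
matrix, for computational biologists who have (i) bulk RNA-seq across
ordered developmental stages with replicates, (ii) a surfaceome/TF gene
annotation, and (iii) a small set of anchor genes defining the state of
interest.

## What it computes

**Screening cascade** (`run_screen()`), applied in fixed order to genes
*g* with expression on the `log2(cpm+1)` scale:

1. Pearson `r(g, a) >= 0.6` for *every* epicardial anchor *a*;
2. surfaceome membership;
3. differential expression early vs late by a nonparametric (M, D)
   statistic: `M = log2((mean_late + c)/(mean_early + c))`,
   `D = |mean_late − mean_early|`, with DE probability the fraction of
   within-condition replicate noise pairs strictly dominated by
   `(|M|, D)`, flagged at `prob > 0.8`;
4. significant negative correlation (`r < 0`, `p < 0.05`) to every
   endothelial anchor (CDH5, PECAM1);
5. top-*k* late/early fold change `(mean_late + c)/(mean_early + c)`;
6. confirmation correlation `r >= 0.6` to the anchors;
7. adult silencing `mean_adult/(mean_late + c) <= 0.05`.

**Upstream-regulator prioritization** (`correlated_deg_set()`,
`tf_intersection()`, `prioritize_tfs()`): genes correlated with a candidate
marker (`r >= 0.6`) that are DE, intersected with annotated transcription
factors, then ranked by their best promoter binding score from a JASPAR-style
position weight matrix: log-odds weights
`w = log2(((n + p·b)/(N + p))/b)`, both strands scanned, scores min-max
normalized to a relative score in [0, 1] (consensus = 1.0).

**Sample structure** (`pca_samples()`, `manhattan_distances()`,
`agnes_cluster()`, `kmeans_samples()`): PCA with variance-explained
fractions and a deterministic sign convention, AGNES agglomeration with
Manhattan distances and Newick export, seeded k-means.

**Synthetic data with planted truth** (`simulate_expression()`,
`simulate_promoters()`): gamma-Poisson counts around a three-stage
trajectory (early 50, late 500, adult 5 mean counts for anchors), planted
surface markers whose noise variance is solved from a target anchor
correlation (default 0.9), anti-correlated endothelial genes, unstructured
background, and promoters carrying a planted motif instance — the oracle
for every end-to-end test.

## Worked example

```r
library(epimarker)

sim <- simulate_expression(sim_config(seed = 7))
sim
#> Synthetic staged expression dataset
#>   genes:  2030  samples: 12
#>   stages: early:4  late:4  adult:4
#>   planted markers: 10; regulator TFs: 5

scr <- run_screen(sim$expr, sim$design, sim$annotation,
                  screen_config(top_k = 10))
scr
#> Surface-marker screen
#>   cascade: input=2030 > anchor=36 > surface=11 > deg=10 > endothelial=10 > topk=10 > confirmation=10 > adult=10
#>   candidates: MKR05, MKR10, MKR07, MKR03, MKR02, MKR08, MKR04, MKR06, MKR01, MKR09
```

Of 2030 genes, 36 correlate with all three anchors, 11 of those are
surface-annotated, and the remaining filters leave exactly the ten planted
markers — no false candidates. `tidy(scr)` returns the per-gene ledger,
`glance(scr)` the cascade counts, `autoplot(scr)` a funnel plot.

The full pipeline adds TF prioritization and sample-structure output:

```r
res <- run_pipeline(pipeline_config(generator = sim_config(),
                                    screen = screen_config(top_k = 10),
                                    seed = 7))
res
#> epimarker pipeline run (seed 7)
#>   candidates: MKR05, MKR10, MKR07, MKR03, MKR02, MKR08, MKR04, MKR06, MKR01, MKR09
#>   top TF for MKR05: GATA4 (relative score 1.000)
#>   PC1 variance explained: 29.3%
```

The planted GATA-like motif in the candidate promoter puts GATA4 at rank 1
with relative binding score 1.0. All artifacts (expression, ledger,
candidates, DE table, promoter FASTA, BED hits, TF ranking, PCA scores,
Newick dendrogram, k-means assignment) are written under the output
directory with a `manifest.json` of md5 checksums; reruns with the same
seed are byte-identical.

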