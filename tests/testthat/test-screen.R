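# helper: expression table whose genes have exactly known correlations to a
# shared anchor profile (three identical anchors)
exact_r_dataset <- function(rs, n = 12) {
  anchor <- c(seq(1, 4, length.out = n / 2), seq(8, 12, length.out = n / 2))
  rows <- list(WT1 = anchor, TBX18 = anchor, ALDH1A2 = anchor)
  for (i in seq_along(rs)) {
    rows[[paste0("gene", i)]] <- vector_with_correlation(anchor, rs[i], seed = i)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("s", seq_len(n))
  expression_table(mat)
}

test_that("anchor intersection applies the r threshold against every anchor", {
  expr <- exact_r_dataset(c(0.61, 0.59, 0.95, -0.8))
  cfg <- screen_config()
  out <- anchor_intersection(expr, cfg)
  expect_setequal(out$genes, c("gene1", "gene3"))
  # per-anchor records retained, with r reproduced by the two-pass oracle
  m <- expr_matrix(expr)
  rec <- out$records[out$records$gene == "gene2" & out$records$anchor == "WT1", ]
  expect_equal(rec$r, pearson_twopass(m["gene2", ], m["WT1", ]),
               tolerance = 1e-10)
  expect_equal(rec$r, 0.59, tolerance = 1e-10)

  # absolute-correlation mode admits strong negatives
  out_abs <- anchor_intersection(expr, screen_config(absolute_r = TRUE))
  expect_true("gene4" %in% out_abs$genes)

  # a copy of an anchor is trivially included and anchors exclude themselves
  expect_false(any(cfg$anchor_ids %in% out$genes))
  expect_error(anchor_intersection(expr[expr$gene != "WT1", ], cfg), "WT1")
})

test_that("anchor intersection equals the brute-force triple filter", {
  sim <- simulate_expression(small_sim_config(seed = 21))
  logexpr <- log_transform(normalize_expression(sim$expr, "cpm"), 1)
  cfg <- screen_config()
  out <- anchor_intersection(logexpr, cfg)
  m <- expr_matrix(logexpr)
  expected <- setdiff(rownames(m)[apply(m, 1, function(x) {
    sd(x) > 0 && all(sapply(cfg$anchor_ids, function(a) {
      pearson_twopass(x, m[a, ]) >= 0.6
    }))
  })], cfg$anchor_ids)
  expect_setequal(out$genes, expected)
})

test_that("surfaceome and DEG filters are plain set intersections", {
  ann <- gene_annotation(c("a", "b", "c"), is_surface = c(TRUE, FALSE, TRUE))
  expect_equal(surfaceome_filter(c("a", "b", "c"), ann), c("a", "c"))
  expect_equal(surfaceome_filter(character(), ann), character())
  expect_warning(got <- surfaceome_filter(c("a", "zzz"), ann), "non-surface")
  expect_equal(got, "a")

  deg <- tibble::tibble(gene = c("a", "b", "c"), is_deg = c(TRUE, FALSE, TRUE))
  expect_equal(deg_overlap(c("a", "b", "c"), deg), c("a", "c"))
  set.seed(31)
  genes <- paste0("g", 1:50)
  flags <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  deg2 <- tibble::tibble(gene = genes, is_deg = flags)
  expect_setequal(deg_overlap(genes, deg2), genes[flags])
})

test_that("endothelial exclusion keeps significant negative correlates only", {
  n <- 12
  endo <- c(seq(10, 6, length.out = n / 2), seq(3, 1, length.out = n / 2))
  mat <- rbind(CDH5 = endo, PECAM1 = endo + 0.05,
               neg = max(endo) - endo + 1,   # exact negated-and-shifted profile
               pos = endo * 2,               # endothelial-like
               noise = vector_with_correlation(endo, -0.2, seed = 3))
  colnames(mat) <- paste0("s", 1:n)
  expr <- expression_table(mat)
  cfg <- screen_config()
  out <- endothelial_exclusion(c("neg", "pos", "noise"), expr, cfg)
  expect_equal(out$genes, "neg")

  # brute-force (r, p) filter on a synthetic instance
  sim <- simulate_expression(small_sim_config(seed = 22))
  logexpr <- log_transform(normalize_expression(sim$expr, "cpm"), 1)
  m <- expr_matrix(logexpr)
  all_genes <- rownames(m)[apply(m, 1, sd) > 0]
  out2 <- endothelial_exclusion(all_genes, logexpr, cfg)
  expected <- all_genes[sapply(all_genes, function(g) {
    all(sapply(cfg$endothelial_ids, function(a) {
      ct <- cor.test(m[g, ], m[a, ])
      ct$estimate < 0 && ct$p.value < 0.05
    }))
  })]
  expect_setequal(out2$genes, expected)
})

test_that("top-k keeps upregulated genes, ranked with lexicographic ties", {
  fcs <- tibble::tibble(gene = c("a", "b", "c"),
                        log2fc = c(2, 1, -0.5))
  cfg <- screen_config(top_k = 3)
  expect_warning(top <- topk_upregulated(c("a", "b", "c"), fcs, cfg), "top_k")
  expect_equal(top, c("a", "b"))

  tied <- tibble::tibble(gene = c("zeta", "alpha", "mid"),
                         log2fc = c(1.5, 1.5, 2.0))
  got <- topk_upregulated(tied$gene, tied, screen_config(top_k = 2))
  expect_equal(got, c("mid", "alpha"))

  set.seed(33)
  rnd <- tibble::tibble(gene = paste0("g", 1:40), log2fc = rnorm(40))
  k <- 7
  got <- topk_upregulated(rnd$gene, rnd, screen_config(top_k = k))
  up <- rnd[rnd$log2fc > 0, ]
  expected <- head(up$gene[order(-up$log2fc, up$gene)], k)
  expect_equal(got, expected)
})

test_that("confirmation filter re-applies the anchor threshold", {
  expr <- exact_r_dataset(c(0.7, 0.5))
  out <- anchor_intersection(expr, screen_config(r_anchor = 0.4))
  kept <- confirm_epicardial_correlation(c("gene1", "gene2"), out$records,
                                         screen_config(r_confirm = 0.6))
  expect_equal(kept, "gene1")
})

test_that("adult ratios separate silenced markers from persistent genes", {
  toy <- toy_staged_dataset()
  # toy values are already-normalized abundances
  scr <- suppressWarnings(run_screen(toy$expr, toy$design, toy$annotation,
                                     screen_config(top_k = 5),
                                     normalized = TRUE))
  ledger <- tidy(scr)
  expect_true(ledger$adult_ratio[ledger$gene == "MKRA"] <= 0.05)
  expect_gt(ledger$adult_ratio[ledger$gene == "PERSA"], 0.5)
  expect_true("MKRA" %in% scr$candidates)
  expect_false("PERSA" %in% scr$candidates)

  # a generator-planted persistent surface gene never becomes a candidate
  sim <- simulate_expression(small_sim_config(seed = 23, n_adult_persistent = 2))
  scr2 <- suppressWarnings(run_screen(sim$expr, sim$design, sim$annotation,
                                      screen_config(top_k = 10)))
  expect_length(intersect(sim$truth$persistent_ids, scr2$candidates), 0)
})

test_that("the cascade shrinks monotonically and recovers planted markers", {
  sim <- simulate_expression(small_sim_config(seed = 7))
  scr <- run_screen(sim$expr, sim$design, sim$annotation,
                    screen_config(top_k = 5))
  expect_true(all(diff(scr$stage_counts) <= 0))
  expect_gte(length(intersect(scr$candidates, sim$truth$planted_marker_ids)), 4)
  # ledger covers every input gene exactly once with all stage flags
  ledger <- tidy(scr)
  expect_equal(sort(ledger$gene), sort(sim$expr$gene))
  flag_cols <- c("passed_anchor", "passed_surface", "passed_deg",
                 "passed_endothelial", "passed_topk", "passed_confirmation",
                 "passed_adult", "is_candidate")
  expect_false(any(is.na(ledger[flag_cols])))
  # candidacy implies every stage flag
  cand <- ledger[ledger$is_candidate, flag_cols]
  expect_true(all(as.matrix(cand)))
  expect_equal(unname(scr$stage_counts["adult"]), length(scr$candidates))
  # glance() mirrors the cascade counts
  g <- glance(scr)
  expect_equal(g$n_candidates, length(scr$candidates))
})

test_that("shuffling gene rows leaves the candidate set unchanged", {
  sim <- simulate_expression(small_sim_config(seed = 11))
  scr1 <- run_screen(sim$expr, sim$design, sim$annotation,
                     screen_config(top_k = 5))
  set.seed(99)
  shuffled <- sim$expr[sample(nrow(sim$expr)), ]
  scr2 <- run_screen(shuffled, sim$design, sim$annotation,
                     screen_config(top_k = 5))
  expect_setequal(scr1$candidates, scr2$candidates)
  expect_equal(scr1$stage_counts, scr2$stage_counts)
})

test_that("missing adult stage skips the final filter with a warning", {
  sim <- simulate_expression(small_sim_config(
    seed = 13, stages = c(early = 4, late = 4),
    anchor_trajectory = c(early = 50, late = 500)))
  expect_warning(
    scr <- run_screen(sim$expr, sim$design, sim$annotation,
                      screen_config(top_k = 5)),
    "adult")
  expect_true(all(is.na(tidy(scr)$adult_ratio)))
})
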