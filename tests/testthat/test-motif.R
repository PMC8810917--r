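test_that("PWM log-odds cells match the defining formula", {
  p <- pfm(rbind(c(10, 5), c(0, 5), c(0, 5), c(0, 5)), id = "M")
  w0 <- build_pwm(p, pseudocount = 0)
  expect_equal(unname(w0$weights["A", 1]), 2)   # log2((10/10)/0.25)
  expect_equal(unname(w0$weights[, 2]), rep(0, 4))  # background-identical column

  set.seed(51)
  counts <- matrix(sample(0:20, 24, replace = TRUE), 4, 6)
  counts[2, colSums(counts) == 0] <- 3
  p2 <- pfm(counts, id = "R")
  w1 <- build_pwm(p2, pseudocount = 1)
  bg <- 0.25
  for (i in 1:4) for (j in 1:6) {
    expected <- log2(((counts[i, j] + 1 * bg) / (sum(counts[, j]) + 1)) / bg)
    expect_equal(unname(w1$weights[i, j]), expected, tolerance = 1e-12)
  }
  expect_equal(w1$score_min, sum(apply(w1$weights, 2, min)))
  expect_equal(w1$score_max, sum(apply(w1$weights, 2, max)))
  expect_gte(w1$score_max, w1$score_min)
})

test_that("consensus scores exactly 1.0 and strand symmetry holds", {
  pwm <- build_pwm(plant_pfm())
  cons <- pwm_consensus(pwm)
  expect_equal(cons, "AAGATCCG")
  hit <- scan_promoter(pwm, cons, threshold = 0)
  best <- hit[which.max(hit$rel_score), ]
  expect_equal(best$rel_score, 1.0)
  expect_equal(best$start, 0L)
  expect_equal(best$end, 8L)
  expect_equal(best$strand, "+")

  rc_hit <- scan_promoter(pwm, epimarker:::revcomp(cons), threshold = 0)
  rc_best <- rc_hit[which.max(rc_hit$rel_score), ]
  expect_equal(rc_best$rel_score, 1.0)
  expect_equal(rc_best$strand, "-")

  set.seed(52)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    fwd <- max(scan_promoter(pwm, s, threshold = 0)$rel_score)
    rev <- max(scan_promoter(pwm, epimarker:::revcomp(s), threshold = 0)$rel_score)
    expect_equal(fwd, rev, tolerance = 1e-12)
  }
})

test_that("the scanner equals the brute-force window oracle exactly", {
  set.seed(53)
  for (i in 1:100) {
    width <- sample(4:10, 1)
    counts <- matrix(sample(0:15, 4 * width, replace = TRUE), 4, width)
    counts[3, colSums(counts) == 0] <- 2
    pwm <- build_pwm(pfm(counts, id = "R"), pseudocount = 1)
    s <- paste(sample(c("A", "C", "G", "T"), sample(width:50, 1),
                      replace = TRUE), collapse = "")
    got <- scan_promoter(pwm, s, threshold = 0)
    bf <- scan_bruteforce(pwm$weights, s, pwm$score_min, pwm$score_max)
    bf <- bf[order(bf$start, bf$strand), ]
    expect_equal(got$start, bf$start)
    expect_equal(got$strand, bf$strand)
    expect_equal(got$score, bf$score, tolerance = 1e-12)
    expect_equal(got$rel_score, bf$rel_score, tolerance = 1e-12)
  }
})

test_that("windows containing N are skipped and short sequences error", {
  pwm <- build_pwm(toy_pfm())
  hits <- scan_promoter(pwm, "ACNAACGAT", threshold = 0)
  # windows at starts 0..2 contain the N at position 2 (0-based)
  expect_true(all(hits$start >= 3))
  expect_error(scan_promoter(pwm, "ACG"), "shorter")
  expect_error(scan_promoter(pwm, "ACGTB"), "invalid")
})

test_that("relative scores ignore a constant added to one PWM column", {
  pwm <- build_pwm(toy_pfm())
  shifted <- pwm
  shifted$weights[, 2] <- shifted$weights[, 2] + 1.7
  shifted$score_min <- sum(apply(shifted$weights, 2, min))
  shifted$score_max <- sum(apply(shifted$weights, 2, max))
  s <- "ACGATTACGGATCCAAGT"
  a <- scan_promoter(pwm, s, threshold = 0)
  b <- scan_promoter(shifted, s, threshold = 0)
  expect_equal(a$rel_score, b$rel_score, tolerance = 1e-12)
})

test_that("candidate-correlated DEG set applies both filters", {
  n <- 12
  cand <- c(seq(1, 3, length.out = 6), seq(7, 10, length.out = 6))
  mat <- rbind(CAND = cand,
               copy = cand * 2 + 1,
               near = vector_with_correlation(cand, 0.59, seed = 2),
               above = vector_with_correlation(cand, 0.7, seed = 3),
               anti = vector_with_correlation(cand, -0.9, seed = 4))
  colnames(mat) <- paste0("s", 1:n)
  expr <- expression_table(mat)
  deg <- tibble::tibble(gene = rownames(mat),
                        is_deg = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  out <- correlated_deg_set(expr, deg, "CAND", r_min = 0.6)
  expect_true("copy" %in% out$gene)        # exact copy, DEG
  expect_false("near" %in% out$gene)       # r = 0.59 < 0.6
  expect_false("above" %in% out$gene)      # r ok but not a DEG
  expect_false("CAND" %in% out$gene)       # candidate itself excluded
  expect_error(correlated_deg_set(expr, deg, "MISSING"), "MISSING")

  # brute-force joint filter on a synthetic instance
  sim <- simulate_expression(small_sim_config(seed = 24))
  logexpr <- log_transform(normalize_expression(sim$expr, "cpm"), 1)
  m <- expr_matrix(logexpr)
  degs <- deg_test(normalize_expression(sim$expr, "cpm"), sim$design)
  candg <- sim$truth$planted_marker_ids[1]
  out2 <- correlated_deg_set(logexpr, degs, candg, 0.6)
  expected <- setdiff(rownames(m)[apply(m, 1, function(x) {
    sd(x) > 0 && pearson_twopass(x, m[candg, ]) >= 0.6
  })], candg)
  expected <- intersect(expected, degs$gene[degs$is_deg])
  expect_setequal(out2$gene, expected)
})

test_that("TF intersection preserves order and prioritization ranks planted first", {
  ann <- gene_annotation(c("GATA4", "x", "TF2", "y"),
                         is_tf = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tf_intersection(c("y", "TF2", "x", "GATA4"), ann),
               c("TF2", "GATA4"))
  expect_equal(tf_intersection(character(), ann), character())

  planted <- plant_pfm()
  cfg <- sim_config(seed = 41, promoter_length = 300)
  prom <- simulate_promoters(cfg, planted, target_ids = "CAND")
  set.seed(42)
  decoys <- lapply(1:5, function(i) random_pfm(8, id = paste0("D", i)))
  library <- c(list(GATA4 = planted),
               setNames(decoys, paste0("TF", 1:5)))
  ranking <- prioritize_tfs(c("GATA4", paste0("TF", 1:5), "NOMOTIF"),
                            library, prom$seqs[["CAND"]])
  expect_equal(ranking$tf[1], "GATA4")
  expect_equal(ranking$best_rel_score[1], 1.0)
  expect_true(is.na(ranking$best_rel_score[ranking$tf == "NOMOTIF"]))
  # each TF's best score equals its independent brute-force best
  for (tf in paste0("TF", 1:3)) {
    pwm <- build_pwm(library[[tf]])
    bf <- scan_bruteforce(pwm$weights, prom$seqs[["CAND"]],
                          pwm$score_min, pwm$score_max)
    expect_equal(ranking$best_rel_score[ranking$tf == tf], max(bf$rel_score),
                 tolerance = 1e-12)
  }
  expect_error(prioritize_tfs("GATA4", list(), "ACGT"), "empty")
})

test_that("a threshold no motif reaches still yields a full ranking", {
  pwm_lib <- list(TFA = toy_pfm())
  ranking <- prioritize_tfs("TFA", pwm_lib, "TTTTTTTTTT", threshold = 0.99)
  expect_equal(nrow(ranking), 1)
  expect_false(ranking$above_threshold[1])
})
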