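# Independent oracles used to cross-check package computations. These are
# deliberately naive (two-pass formulas, exhaustive loops, full enumeration)
# and share no code with the implementation paths they verify.

# two-pass product-moment correlation
pearson_twopass <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive within-condition (|M|, D) noise pool
pool_bruteforce <- function(mat, samples_a, samples_b, c = 1) {
  rows <- list()
  for (cond in list(samples_a, samples_b)) {
    if (length(cond) < 2) next
    for (i in seq_len(length(cond) - 1)) {
      for (j in (i + 1):length(cond)) {
        xi <- mat[, cond[i]]; xj <- mat[, cond[j]]
        rows[[length(rows) + 1]] <-
          data.frame(m = abs(log2((xi + c) / (xj + c))), d = abs(xi - xj))
      }
    }
  }
  do.call(rbind, rows)
}

# exhaustive double-loop dominance probability per gene
deg_prob_bruteforce <- function(mat, samples_a, samples_b, c = 1) {
  pool <- pool_bruteforce(mat, samples_a, samples_b, c)
  sapply(rownames(mat), function(g) {
    ma <- mean(mat[g, samples_a]); mb <- mean(mat[g, samples_b])
    M <- abs(log2((mb + c) / (ma + c))); D <- abs(mb - ma)
    hits <- 0
    for (k in seq_len(nrow(pool))) {
      if (M > pool$m[k] && D > pool$d[k]) hits <- hits + 1
    }
    hits / nrow(pool)
  })
}

# naive per-window PWM scan on both strands, plus-strand coordinates
scan_bruteforce <- function(weights, sequence, score_min, score_max) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- ncol(weights)
  out <- NULL
  for (start in 0:(length(chars) - L)) {
    win <- chars[(start + 1):(start + L)]
    if (any(win == "N")) next
    fwd <- sum(sapply(seq_len(L), function(j) weights[match(win[j], bases), j]))
    rcw <- rev(unname(comp[win]))
    rev_s <- sum(sapply(seq_len(L), function(j) weights[match(rcw[j], bases), j]))
    out <- rbind(out,
                 data.frame(start = start, strand = "+", score = fwd),
                 data.frame(start = start, strand = "-", score = rev_s))
  }
  out$rel_score <- (out$score - score_min) / (score_max - score_min)
  out
}

# minimum-spanning-tree edge weights by Prim's algorithm
mst_edge_weights <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  weights <- numeric(0)
  while (sum(in_tree) < n) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    w <- min(sub)
    pick <- which(!in_tree)[which(apply(sub, 2, min) == w)[1]]
    weights <- c(weights, w)
    in_tree[pick] <- TRUE
  }
  sort(weights)
}

# exhaustive k-partition optimum inertia for small n
kmeans_bruteforce <- function(m, k) {
  n <- nrow(m)
  best <- Inf
  grid <- expand.grid(rep(list(seq_len(k)), n))
  for (r in seq_len(nrow(grid))) {
    assign <- as.integer(grid[r, ])
    if (length(unique(assign)) < k) next
    inertia <- 0
    for (cl in seq_len(k)) {
      pts <- m[assign == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      inertia <- inertia + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, inertia)
  }
  best
}

# vector with exact Pearson correlation `r` to `anchor`
vector_with_correlation <- function(anchor, r, seed = 1) {
  set.seed(seed)
  a <- anchor - mean(anchor)
  repeat {
    u <- rnorm(length(anchor))
    u <- u - mean(u)
    u <- u - a * sum(u * a) / sum(a * a)
    if (sum(u^2) > 1e-12) break
  }
  y <- r * a / sqrt(sum(a^2)) + sqrt(1 - r^2) * u / sqrt(sum(u^2))
  y - min(y) + 1  # shift positive; Pearson is shift-invariant
}
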