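# Upstream-regulator prioritization: intersect candidate-correlated DEGs with
# annotated transcription factors, then score each TF's motif against the
# candidate promoter with a log-odds position weight matrix; hits are
# reported on a min-max relative score in [0, 1] (1.0 = consensus).

BASES <- c("A", "C", "G", "T")

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Build a log-odds position weight matrix from a frequency matrix
#'
#' Per cell, `weight = log2(((count + pseudocount * bg) / (column_total +
#' pseudocount)) / bg)` with background base frequency `bg`. Column minima
#' and maxima are precomputed for min-max relative scoring.
#'
#' @param pfm A [pfm()] object.
#' @param pseudocount Total pseudocount distributed by background; default 1.
#' @param background Base frequencies (A, C, G, T), positive, summing to 1.
#' @return A `pwm` object: list with `id`, `name`, 4 x L `weights`,
#'   `score_min`, `score_max`.
#' @export
build_pwm <- function(pfm, pseudocount = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(pfm, "pfm"))
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-8) {
    abort("background frequencies must be positive and sum to 1")
  }
  counts <- pfm$counts
  totals <- colSums(counts)
  freqs <- sweep(counts + pseudocount * background, 2, totals + pseudocount, "/")
  weights <- log2(freqs / background)
  rownames(weights) <- BASES
  structure(list(id = pfm$id, name = pfm$name, weights = weights,
                 pseudocount = pseudocount, background = background,
                 score_min = sum(apply(weights, 2, min)),
                 score_max = sum(apply(weights, 2, max))),
            class = "pwm")
}

#' Consensus sequence of a PWM
#'
#' The highest-weight base per column (ties broken in A, C, G, T order); by
#' construction it attains the maximum raw score, i.e. relative score 1.
#'
#' @param pwm A `pwm` from [build_pwm()].
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  paste(BASES[apply(pwm$weights, 2, which.max)], collapse = "")
}

# raw log-odds scores of every window start on the plus strand of `seq_chars`
# (an integer vector indexing A=1..T=4, NA for N); NA windows -> NA score
window_scores <- function(pwm, base_idx) {
  L <- ncol(pwm$weights)
  n_win <- length(base_idx) - L + 1L
  scores <- numeric(n_win)
  for (j in seq_len(L)) {
    w <- pwm$weights[, j]
    scores <- scores + w[base_idx[j:(j + n_win - 1L)]]
  }
  unname(scores)
}

#' Scan a promoter sequence with a PWM
#'
#' Scores every window on the requested strands; windows containing `N` are
#' skipped. Minus-strand windows are scored on the reverse complement but
#' reported in plus-strand coordinates (0-based, half-open). Hits at or above
#' the relative-score threshold are returned sorted by start position.
#'
#' @param pwm A `pwm` from [build_pwm()].
#' @param sequence Promoter sequence (A/C/G/T/N).
#' @param threshold Minimum relative score in \[0, 1\]; default 0.8.
#' @param strands Strands to scan, subset of `c("+", "-")`.
#' @param promoter_id Identifier used in the output.
#' @return Tibble (promoter, start, end, strand, score, rel_score, motif).
#' @export
scan_promoter <- function(pwm, sequence, threshold = 0.8,
                          strands = c("+", "-"), promoter_id = "promoter") {
  stopifnot(inherits(pwm, "pwm"))
  sequence <- toupper(sequence)
  L <- ncol(pwm$weights)
  n <- nchar(sequence)
  if (n < L) abort("sequence shorter than motif")
  chars <- strsplit(sequence, "")[[1]]
  if (any(!chars %in% c(BASES, "N"))) abort("invalid characters in sequence")
  idx_fwd <- match(chars, BASES)  # N -> NA
  denom <- pwm$score_max - pwm$score_min
  if (denom <= 0) denom <- 1  # flat motif: every window scores relative 1
  res <- list()
  starts <- 0:(n - L)
  if ("+" %in% strands) {
    sc <- window_scores(pwm, idx_fwd)
    res$plus <- tibble(start = starts, strand = "+", score = sc)
  }
  if ("-" %in% strands) {
    # score the reverse complement, then map window back to plus coordinates
    rc <- revcomp(sequence)
    idx_rev <- match(strsplit(rc, "")[[1]], BASES)
    sc <- rev(window_scores(pwm, idx_rev))
    res$minus <- tibble(start = starts, strand = "-", score = sc)
  }
  hits <- bind_rows(res) |>
    filter(!is.na(.data$score)) |>
    mutate(rel_score = pmin(1, pmax(0, (.data$score - pwm$score_min) / denom)),
           end = .data$start + L,
           promoter = promoter_id, motif = pwm$id) |>
    filter(.data$rel_score >= threshold) |>
    arrange(.data$start, .data$strand) |>
    select("promoter", "start", "end", "strand", "score", "rel_score", "motif")
  hits
}

#' Genes correlated with a candidate that are also differentially expressed
#'
#' @param expr Expression tibble on the correlation scale (e.g.
#'   log2(cpm + 1)).
#' @param deg_records Output of [deg_test()].
#' @param candidate_gene The candidate marker gene id.
#' @param r_min Minimum Pearson correlation to the candidate; default 0.6.
#' @return Tibble (gene, r, p, is_deg) of genes passing both filters,
#'   candidate itself excluded.
#' @export
correlated_deg_set <- function(expr, deg_records, candidate_gene, r_min = 0.6) {
  m <- expr_matrix(validate_expression(expr))
  if (!candidate_gene %in% rownames(m)) {
    abort(paste0("candidate gene absent from matrix: ", candidate_gene))
  }
  recs <- correlate_to_anchors(m, candidate_gene)
  degs <- deg_records$gene[deg_records$is_deg]
  recs |>
    filter(.data$gene != candidate_gene, !is.na(.data$r),
           .data$r >= r_min, .data$gene %in% degs) |>
    left_join(select(deg_records, "gene", "is_deg"), by = "gene") |>
    select("gene", "r", "p", "is_deg")
}

#' Restrict a gene set to annotated transcription factors
#'
#' @param genes Character vector of gene ids.
#' @param annotation Gene annotation tibble.
#' @return Character vector in stable (input) order.
#' @export
tf_intersection <- function(genes, annotation) {
  tfs <- annotation$gene[annotation$is_tf]
  genes[genes %in% tfs]
}

#' Rank transcription factors by best promoter binding score
#'
#' For each TF with a motif in the library, the best relative score over both
#' strands of the candidate promoter; TFs without motifs are listed with a
#' missing score. Sorted descending by best score (ties by TF name).
#'
#' @param tfs Character vector of TF gene ids.
#' @param motif_library Named list of [pfm()] objects, names matching TF ids.
#' @param promoter_seq Candidate promoter sequence.
#' @param threshold Relative-score threshold recorded per TF (column
#'   `above_threshold`); default 0.8.
#' @param pseudocount,background Passed to [build_pwm()].
#' @return Tibble (tf, motif, best_rel_score, best_start, best_strand,
#'   above_threshold).
#' @export
prioritize_tfs <- function(tfs, motif_library, promoter_seq, threshold = 0.8,
                           pseudocount = 1,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length(motif_library) == 0) abort("empty motif library")
  rows <- lapply(tfs, function(tf) {
    if (!tf %in% names(motif_library)) {
      return(tibble(tf = tf, motif = NA_character_,
                    best_rel_score = NA_real_, best_start = NA_integer_,
                    best_strand = NA_character_, above_threshold = NA))
    }
    pwm <- build_pwm(motif_library[[tf]], pseudocount, background)
    hits <- scan_promoter(pwm, promoter_seq, threshold = 0, promoter_id = tf)
    best <- hits |> arrange(dplyr::desc(.data$rel_score), .data$start) |> head(1)
    tibble(tf = tf, motif = pwm$id, best_rel_score = best$rel_score,
           best_start = as.integer(best$start), best_strand = best$strand,
           above_threshold = best$rel_score >= threshold)
  })
  bind_rows(rows) |>
    arrange(dplyr::desc(!is.na(.data$best_rel_score)),
            dplyr::desc(.data$best_rel_score), .data$tf)
}
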