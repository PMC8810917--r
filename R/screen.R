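# The biomarker cascade: genes correlated with every epicardial anchor ->
# surfaceome membership -> differential expression between early and late
# stages -> significant negative correlation to endothelial anchors ->
# top-k late-stage fold change -> confirmation correlation -> silencing in
# the adult stage. Every gene keeps a full per-stage ledger.

#' Screen configuration
#'
#' @param anchor_ids Epicardial anchor genes (default WT1, TBX18, ALDH1A2).
#' @param endothelial_ids Endothelial anchor genes (default CDH5, PECAM1).
#' @param r_anchor Minimum Pearson correlation to every anchor; default 0.6.
#' @param absolute_r If `TRUE`, apply `r_anchor` to `|r|` instead of `r`
#'   (absolute-correlation mode); default `FALSE` since the anchors rise
#'   together.
#' @param alpha Two-sided significance level for the endothelial exclusion;
#'   default 0.05.
#' @param top_k Number of top fold-change genes carried to confirmation;
#'   default 3.
#' @param r_confirm Minimum confirmation correlation; default 0.6.
#' @param adult_max_fraction Maximum adult/late mean ratio counted as "not
#'   expressed in adult"; default 0.05.
#' @param pseudocount Shared pseudocount for fold change and adult ratio.
#' @param deg_q DE probability threshold; default 0.8.
#' @param early_stage,late_stage,adult_stage Stage labels; `adult_stage = NULL`
#'   skips the adult-exclusion stage.
#' @return A `screen_config` list.
#' @export
screen_config <- function(anchor_ids = c("WT1", "TBX18", "ALDH1A2"),
                          endothelial_ids = c("CDH5", "PECAM1"),
                          r_anchor = 0.6, absolute_r = FALSE,
                          alpha = 0.05, top_k = 3, r_confirm = 0.6,
                          adult_max_fraction = 0.05, pseudocount = 1,
                          deg_q = 0.8, early_stage = "early",
                          late_stage = "late", adult_stage = "adult") {
  if (length(intersect(anchor_ids, endothelial_ids)) > 0) {
    abort("anchor and endothelial sets must be disjoint")
  }
  for (nm in c("r_anchor", "r_confirm")) {
    v <- get(nm)
    if (v < -1 || v > 1) abort(paste0(nm, " must be in [-1, 1]"))
  }
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  if (top_k < 1) abort("top_k must be at least 1")
  if (adult_max_fraction < 0) abort("adult_max_fraction must be non-negative")
  structure(as.list(environment())[c(
    "anchor_ids", "endothelial_ids", "r_anchor", "absolute_r", "alpha",
    "top_k", "r_confirm", "adult_max_fraction", "pseudocount", "deg_q",
    "early_stage", "late_stage", "adult_stage")], class = "screen_config")
}

#' Genes correlated with every epicardial anchor
#'
#' @param expr Expression tibble on the correlation scale.
#' @param config A [screen_config()].
#' @return List with `genes` (character vector, anchors excluded) and
#'   `records` (long correlation tibble retained for the ledger).
#' @export
anchor_intersection <- function(expr, config) {
  m <- expr_matrix(validate_expression(expr))
  recs <- correlate_to_anchors(m, config$anchor_ids)
  rr <- if (config$absolute_r) abs(recs$r) else recs$r
  pass <- recs |>
    mutate(ok = !is.na(rr) & rr >= config$r_anchor) |>
    group_by(.data$gene) |>
    summarise(ok = all(.data$ok), .groups = "drop")
  genes <- setdiff(pass$gene[pass$ok], config$anchor_ids)
  # keep input row order
  genes <- rownames(m)[rownames(m) %in% genes]
  list(genes = genes, records = recs)
}

#' Restrict to surfaceome members
#'
#' Genes missing from the annotation are treated as non-surface, with a
#' warning.
#'
#' @param genes Character vector.
#' @param annotation Gene annotation tibble.
#' @return Character vector.
#' @export
surfaceome_filter <- function(genes, annotation) {
  unknown <- setdiff(genes, annotation$gene)
  if (length(unknown) > 0) {
    warn(paste0(length(unknown), " gene(s) missing from annotation, ",
                "treated as non-surface"))
  }
  genes[genes %in% annotation$gene[annotation$is_surface]]
}

#' Restrict to differentially expressed genes
#'
#' @param genes Character vector.
#' @param deg_records Output of [deg_test()].
#' @return Character vector.
#' @export
deg_overlap <- function(genes, deg_records) {
  genes[genes %in% deg_records$gene[deg_records$is_deg]]
}

#' Keep genes significantly negatively correlated with endothelial anchors
#'
#' A gene survives when \code{r < 0} and \code{p < alpha} against every
#' endothelial anchor (two-sided t test on the correlation coefficient).
#'
#' @param genes Character vector.
#' @param expr Expression tibble on the correlation scale.
#' @param config A [screen_config()].
#' @return List with `genes` and `records`.
#' @export
endothelial_exclusion <- function(genes, expr, config) {
  m <- expr_matrix(validate_expression(expr))
  recs <- correlate_to_anchors(m, config$endothelial_ids)
  pass <- recs |>
    mutate(ok = !is.na(.data$r) & .data$r < 0 & .data$p < config$alpha) |>
    group_by(.data$gene) |>
    summarise(ok = all(.data$ok), .groups = "drop")
  keep <- pass$gene[pass$ok]
  list(genes = genes[genes %in% keep], records = recs)
}

#' Top late-stage upregulated genes by fold change
#'
#' Genes with positive `log2fc`, sorted descending by `log2fc` (ties broken
#' lexicographically by gene id), truncated to `top_k`.
#'
#' @param genes Character vector.
#' @param fold_changes Output of [fold_change()].
#' @param config A [screen_config()].
#' @return Character vector, ranked.
#' @export
topk_upregulated <- function(genes, fold_changes, config) {
  fc <- fold_changes |>
    filter(.data$gene %in% genes, .data$log2fc > 0) |>
    arrange(dplyr::desc(.data$log2fc), .data$gene)
  if (nrow(fc) < config$top_k) {
    warn(paste0("only ", nrow(fc), " upregulated gene(s) available for top_k = ",
                config$top_k))
  }
  head(fc$gene, config$top_k)
}

#' Confirmation correlation against the epicardial anchors
#'
#' @param genes Character vector.
#' @param records Anchor correlation records (from [anchor_intersection()]).
#' @param config A [screen_config()].
#' @return Character vector of genes with \code{r >= r_confirm} to every
#'   anchor.
#' @export
confirm_epicardial_correlation <- function(genes, records, config) {
  pass <- records |>
    mutate(ok = !is.na(.data$r) & .data$r >= config$r_confirm) |>
    group_by(.data$gene) |>
    summarise(ok = all(.data$ok), .groups = "drop")
  genes[genes %in% pass$gene[pass$ok]]
}

#' Run the full biomarker screen
#'
#' Normalizes (cpm), log-transforms, computes the nonparametric DE call
#' between the early and late stages, then applies the cascade in fixed
#' order: anchor correlation, surfaceome, DE overlap, endothelial exclusion,
#' fold-change top-k, confirmation correlation, adult exclusion. Fold changes
#' are computed on the normalized linear scale; correlations on the
#' log2(cpm + 1) scale.
#'
#' @param expr Raw expression tibble.
#' @param design Stage design tibble.
#' @param annotation Gene annotation tibble.
#' @param config A [screen_config()].
#' @param normalized If `TRUE`, `expr` is taken as already normalized and cpm
#'   is skipped.
#' @return A `marker_screen` object: list with `candidates` (character
#'   vector), `ledger` (per-gene stage flags and statistics), `stage_counts`,
#'   `records` (correlation tables), `deg`, `fold_changes`, `config`.
#' @export
run_screen <- function(expr, design, annotation, config = screen_config(),
                       normalized = FALSE) {
  expr <- validate_expression(expr)
  check_design_matches(expr, design)
  missing_anchors <- setdiff(c(config$anchor_ids, config$endothelial_ids),
                             expr$gene)
  if (length(missing_anchors) > 0) {
    abort(paste0("anchor gene(s) absent from matrix: ",
                 paste(missing_anchors, collapse = ", ")))
  }
  norm <- if (normalized) expr else normalize_expression(expr, "cpm")
  logexpr <- log_transform(norm, 1)

  deg <- deg_test(norm, design, config$early_stage, config$late_stage,
                  pseudocount = config$pseudocount, q = config$deg_q)
  fcs <- fold_change(norm, design, config$early_stage, config$late_stage,
                     pseudocount = config$pseudocount)

  s1 <- anchor_intersection(logexpr, config)
  genes1 <- s1$genes
  genes2 <- surfaceome_filter(genes1, annotation)
  genes3 <- deg_overlap(genes2, deg)
  s4 <- endothelial_exclusion(genes3, logexpr, config)
  genes4 <- s4$genes
  genes5 <- topk_upregulated(genes4, fcs, config)
  genes6 <- confirm_epicardial_correlation(genes5, s1$records, config)

  m <- expr_matrix(norm)
  have_adult <- !is.null(config$adult_stage) &&
    config$adult_stage %in% as.character(design$stage)
  if (have_adult) {
    mean_adult <- rowMeans(m[, stage_samples(design, config$adult_stage),
                             drop = FALSE])
    mean_late <- rowMeans(m[, stage_samples(design, config$late_stage),
                            drop = FALSE])
    adult_ratio <- (mean_adult) / (mean_late + config$pseudocount)
    pass_adult_all <- adult_ratio <= config$adult_max_fraction
    genes7 <- genes6[pass_adult_all[genes6]]
  } else {
    warn("no adult stage in design: adult-exclusion stage skipped")
    adult_ratio <- setNames(rep(NA_real_, nrow(m)), rownames(m))
    pass_adult_all <- setNames(rep(NA, nrow(m)), rownames(m))
    genes7 <- genes6
  }

  anchor_r <- s1$records |>
    select("gene", "anchor", "r") |>
    tidyr::pivot_wider(names_from = "anchor", values_from = "r",
                       names_prefix = "r_")
  fc_rank <- fcs |>
    filter(.data$log2fc > 0) |>
    arrange(dplyr::desc(.data$log2fc), .data$gene) |>
    mutate(fc_rank = dplyr::row_number()) |>
    select("gene", "fc_rank")

  ledger <- tibble(gene = expr$gene) |>
    left_join(anchor_r, by = "gene") |>
    mutate(passed_anchor = .data$gene %in% genes1) |>
    left_join(select(annotation, "gene", "is_surface"), by = "gene") |>
    mutate(is_surface = !is.na(.data$is_surface) & .data$is_surface,
           passed_surface = .data$gene %in% genes2) |>
    left_join(select(deg, "gene", "prob", "is_deg"), by = "gene") |>
    mutate(passed_deg = .data$gene %in% genes3,
           passed_endothelial = .data$gene %in% genes4) |>
    left_join(select(fcs, "gene", "log2fc"), by = "gene") |>
    left_join(fc_rank, by = "gene") |>
    mutate(passed_topk = .data$gene %in% genes5,
           passed_confirmation = .data$gene %in% genes6,
           adult_ratio = unname(adult_ratio[.data$gene]),
           passed_adult = .data$gene %in% genes7 |
             (!have_adult & .data$gene %in% genes6),
           is_candidate = .data$gene %in% genes7)

  counts <- c(input = nrow(expr), anchor = length(genes1),
              surface = length(genes2), deg = length(genes3),
              endothelial = length(genes4), topk = length(genes5),
              confirmation = length(genes6), adult = length(genes7))
  structure(list(candidates = genes7, ledger = ledger, stage_counts = counts,
                 records = list(anchor = s1$records, endothelial = s4$records),
                 deg = deg, fold_changes = fcs, config = config),
            class = "marker_screen")
}

#' @export
print.marker_screen <- function(x, ...) {
  cat("Surface-marker screen\n")
  cat("  cascade: ",
      paste(names(x$stage_counts), x$stage_counts, sep = "=", collapse = " > "),
      "\n", sep = "")
  cat("  candidates: ",
      if (length(x$candidates)) paste(x$candidates, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' @describeIn run_screen Per-gene cascade ledger as a tibble.
#' @param x A `marker_screen` object.
#' @param ... Unused.
#' @export
tidy.marker_screen <- function(x, ...) x$ledger

#' @describeIn run_screen One-row summary: stage survivor counts and final
#'   candidate count.
#' @export
glance.marker_screen <- function(x, ...) {
  as_tibble(as.list(x$stage_counts)) |>
    mutate(n_candidates = length(x$candidates))
}

#' @describeIn run_screen Funnel plot of cascade survivor counts.
#' @param object A `marker_screen` object.
#' @export
autoplot.marker_screen <- function(object, ...) {
  df <- tibble(stage = factor(names(object$stage_counts),
                              levels = names(object$stage_counts)),
               n = as.integer(object$stage_counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cascade stage", y = "surviving genes (log scale)",
                  title = "Marker-screen cascade") +
    ggplot2::theme_minimal()
}
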