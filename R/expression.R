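# Tabular containers used throughout: an expression table is a tibble whose
# first column `gene` holds unique identifiers and whose remaining columns are
# non-negative numeric sample values; a stage design is a tibble with columns
# (sample, stage, replicate[, line]) and an ordered stage vocabulary.

#' Assemble an expression table
#'
#' Builds the canonical gene-by-sample expression tibble from a numeric matrix
#' and validates it: unique gene and sample identifiers, no negative values,
#' no missing cells.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers.
#' @param sample_ids Character vector of unique sample identifiers.
#' @return A tibble with a `gene` column followed by one numeric column per
#'   sample.
#' @export
expression_table <- function(values, gene_ids = rownames(values),
                             sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("gene_ids and sample_ids are required")
  }
  expr <- bind_cols(tibble(gene = as.character(gene_ids)),
                    as_tibble(values, .name_repair = "minimal") |>
                      setNames(as.character(sample_ids)))
  validate_expression(expr)
}

#' Validate an expression table
#'
#' @param expr Expression tibble (`gene` column + numeric sample columns).
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_expression <- function(expr) {
  if (!is.data.frame(expr) || names(expr)[1] != "gene") {
    abort("an expression table must have 'gene' as its first column")
  }
  if (ncol(expr) < 2) abort("expression table has no sample columns")
  if (anyDuplicated(expr$gene)) {
    dup <- unique(expr$gene[duplicated(expr$gene)])
    abort(paste0("duplicate gene id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(names(expr)[-1])) abort("duplicate sample ids")
  vals <- as.matrix(expr[-1])
  if (!is.numeric(vals)) abort("non-numeric expression values")
  if (anyNA(vals)) abort("missing expression values")
  if (any(vals < 0)) abort("negative expression values")
  as_tibble(expr)
}

#' Extract the numeric matrix from an expression table
#'
#' @inheritParams validate_expression
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
expr_matrix <- function(expr) {
  m <- as.matrix(expr[-1])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

#' Construct a stage design table
#'
#' @param sample Sample identifiers (must match expression columns).
#' @param stage Stage label per sample.
#' @param replicate Replicate index per sample.
#' @param line Optional cell-line label.
#' @param stage_levels Ordered stage vocabulary, earliest first.
#' @return A tibble with `stage` as an ordered factor.
#' @export
stage_design <- function(sample, stage, replicate = NULL, line = NULL,
                         stage_levels = c("early", "late", "adult")) {
  if (!all(stage %in% stage_levels)) {
    abort(paste0("unknown stage label(s): ",
                 paste(setdiff(unique(stage), stage_levels), collapse = ", ")))
  }
  if (anyDuplicated(sample)) abort("duplicate sample ids in design")
  tb <- tibble(sample = as.character(sample),
               stage = factor(stage, levels = stage_levels, ordered = TRUE))
  tb$replicate <- if (is.null(replicate)) {
    stats::ave(seq_along(sample), stage, FUN = seq_along)
  } else as.integer(replicate)
  if (!is.null(line)) tb$line <- as.character(line)
  tb
}

# samples belonging to one stage, in design order
stage_samples <- function(design, stage) {
  s <- design$sample[design$stage == stage]
  if (length(s) == 0) abort(paste0("unknown or empty stage: ", stage))
  s
}

check_design_matches <- function(expr, design) {
  samples <- names(expr)[-1]
  missing <- setdiff(samples, design$sample)
  if (length(missing) > 0) {
    abort(paste0("samples absent from design: ", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Construct a gene annotation table
#'
#' Per-gene flags used by the screen: surfaceome membership, transcription
#' factor membership, and a role label (`anchor_epicardial`,
#' `anchor_endothelial`, `candidate`, `other`).
#'
#' @param gene Gene identifiers.
#' @param is_surface,is_tf Logical flags.
#' @param role Role label per gene.
#' @return A tibble with one row per gene.
#' @export
gene_annotation <- function(gene, is_surface = FALSE, is_tf = FALSE,
                            role = "other") {
  roles <- c("anchor_epicardial", "anchor_endothelial", "candidate", "other")
  tb <- tibble(gene = as.character(gene),
               is_surface = rep_len(as.logical(is_surface), length(gene)),
               is_tf = rep_len(as.logical(is_tf), length(gene)),
               role = rep_len(as.character(role), length(gene)))
  if (!all(tb$role %in% roles)) {
    abort(paste0("role must be one of: ", paste(roles, collapse = ", ")))
  }
  if (anyDuplicated(tb$gene)) abort("duplicate gene ids in annotation")
  tb
}
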