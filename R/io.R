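# On-disk dialects: TSV tables (decimal point, UTF-8), JASPAR text PFMs,
# FASTA promoters, BED6-like hit tables (0-based half-open), Newick trees.

#' Read a gene-by-sample expression TSV
#'
#' Expects a tab-separated table whose first header cell is `gene` and whose
#' remaining header cells are sample ids, one gene per row. Parsing is strict:
#' duplicate gene ids, negative, missing or non-numeric cells and ragged rows
#' are errors naming the offender.
#'
#' @param path File path.
#' @return An expression tibble (see [expression_table()]).
#' @export
read_expression_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "gene") {
    abort(paste0(path, ": first header cell must be 'gene'"))
  }
  tb <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, lazy = FALSE))
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    abort(paste0(path, ": parse error at line ", probs$row[1] + 1L,
                 " (", probs$expected[1], ", got '", probs$actual[1], "')"))
  }
  validate_expression(tb)
}

#' Write an expression table as TSV
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read / write a stage design TSV
#'
#' Columns: sample, stage, replicate and optionally line.
#'
#' @param path File path.
#' @param stage_levels Ordered stage vocabulary.
#' @return A design tibble.
#' @export
read_design_tsv <- function(path, stage_levels = c("early", "late", "adult")) {
  tb <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stage_design(tb$sample, tb$stage,
               replicate = tb$replicate,
               line = if ("line" %in% names(tb)) tb$line else NULL,
               stage_levels = stage_levels)
}

#' @rdname read_design_tsv
#' @param design Design tibble.
#' @export
write_design_tsv <- function(design, path) {
  out <- design
  out$stage <- as.character(out$stage)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a gene annotation TSV
#'
#' @param path File path.
#' @return An annotation tibble.
#' @export
read_annotation_tsv <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    is_surface = readr::col_logical(),
    is_tf = readr::col_logical(),
    role = readr::col_character()
  ), progress = FALSE)
  gene_annotation(tb$gene, tb$is_surface, tb$is_tf, tb$role)
}

#' @rdname read_annotation_tsv
#' @param annotation Annotation tibble.
#' @export
write_annotation_tsv <- function(annotation, path) {
  readr::write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

#' Read a JASPAR-format position frequency matrix
#'
#' JASPAR text format: a header line starting with `>` carrying the matrix id
#' and name, then four rows `A [ n1 n2 ... ]` in A, C, G, T order. Brackets
#' are optional. Counts are parsed as reals; all rows must have equal length.
#'
#' @param path File path.
#' @return A `pfm` object: list with `id`, `name` and a 4 x L `counts` matrix
#'   with rownames A, C, G, T.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 5 || !startsWith(lines[1], ">")) {
    abort(paste0(path, ": not a JASPAR PFM (expected '>' header + 4 base rows)"))
  }
  hdr <- strsplit(sub("^>\\s*", "", lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[2:5], function(l) {
    base <- substr(trimws(l), 1, 1)
    nums <- gsub("[][]", " ", sub("^\\s*[ACGT]", "", trimws(l)))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    if (anyNA(vals)) abort(paste0(path, ": non-numeric count in row ", base))
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, `[[`, "", "base")
  if (!identical(bases, c("A", "C", "G", "T"))) {
    abort(paste0(path, ": base rows must be A, C, G, T in order (got ",
                 paste(bases, collapse = ","), ")"))
  }
  lens <- vapply(rows, function(r) length(r$vals), 1L)
  if (length(unique(lens)) != 1) {
    abort(paste0(path, ": unequal row lengths (", paste(lens, collapse = ","), ")"))
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(counts) <- bases
  pfm(counts, id = hdr[1], name = if (length(hdr) > 1) hdr[2] else hdr[1])
}

#' Construct a position frequency matrix object
#'
#' @param counts 4 x L non-negative numeric matrix, rows A, C, G, T.
#' @param id Motif identifier.
#' @param name Motif name (e.g. the transcription factor it belongs to).
#' @return A `pfm` object.
#' @export
pfm <- function(counts, id = "motif", name = id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("a PFM needs exactly 4 base rows")
  rownames(counts) <- c("A", "C", "G", "T")
  if (ncol(counts) < 1) abort("a PFM needs at least one column")
  if (any(counts < 0) || anyNA(counts)) abort("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0)) abort("every PFM column needs a positive count")
  structure(list(id = id, name = name, counts = counts), class = "pfm")
}

#' @rdname read_jaspar_pfm
#' @param x A `pfm` object.
#' @export
write_jaspar_pfm <- function(x, path) {
  stopifnot(inherits(x, "pfm"))
  rows <- vapply(c("A", "C", "G", "T"), function(b) {
    paste0(b, " [ ", paste(format(x$counts[b, ], trim = TRUE), collapse = " "), " ]")
  }, "")
  writeLines(c(paste0(">", x$id, " ", x$name), rows), path)
  invisible(path)
}

#' Read a promoter FASTA
#'
#' Accepts multi-line records, uppercases sequences and rejects characters
#' outside A, C, G, T, N. An empty file is an error.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  # read letters verbatim first (readDNAStringSet silently drops codes it
  # does not know), then validate against the A/C/G/T/N alphabet
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0(path, ": empty FASTA"))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0(path, ": invalid characters in record '",
                 names(seqs)[bad][1], "'"))
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0) abort("refusing to write an empty FASTA")
  set <- Biostrings::DNAStringSet(unname(toupper(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Write motif hits as a BED6-like table
#'
#' Columns: sequence id, start (0-based), end (half-open), motif id, relative
#' score, strand.
#'
#' @param hits Hit tibble from [scan_promoter()].
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- tibble(chrom = hits$promoter, start = hits$start, end = hits$end,
                name = hits$motif, score = hits$rel_score, strand = hits$strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Serialize a merge tree as a Newick string
#'
#' Leaves carry sample ids; branch lengths are derived from merge heights so
#' that each leaf sits at depth equal to the height of its last merge.
#'
#' @param tree A `merge_tree` from [agnes_cluster()].
#' @return Single Newick string terminated by `;`.
#' @export
newick_string <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  merge <- tree$merge
  height <- tree$height
  labels <- tree$labels
  node_str <- function(id, parent_h) {
    if (id < 0) {
      paste0(labels[-id], ":", format(parent_h, digits = 10))
    } else {
      h <- height[id]
      paste0("(", node_str(merge[id, 1], h), ",", node_str(merge[id, 2], h),
             "):", format(parent_h - h, digits = 10))
    }
  }
  root <- nrow(merge)
  paste0("(", node_str(merge[root, 1], height[root]), ",",
         node_str(merge[root, 2], height[root]), ");")
}

#' @rdname newick_string
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}
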