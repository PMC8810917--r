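# End-to-end orchestration: simulate (or load) a dataset, run the screen,
# the TF prioritization and the sample-structure analyses, and write every
# artifact plus a machine-readable manifest with input checksums so reruns
# are verifiably identical.

#' Pipeline configuration
#'
#' Bundles the stage configurations and the master seed. Sub-seeds are
#' derived per stage so stages are independently reproducible.
#'
#' @param generator A [sim_config()].
#' @param screen A [screen_config()].
#' @param candidate_gene Gene whose upstream regulators are prioritized;
#'   default the first planted marker.
#' @param tf_r_min Correlation threshold for the candidate-correlated DEG
#'   set; default 0.6.
#' @param motif_threshold Relative-score threshold for promoter hits.
#' @param motif_pseudocount PWM pseudocount.
#' @param kmeans_k Number of k-means clusters; default number of stages.
#' @param seed Master seed, overriding the generator seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = sim_config(),
                            screen = screen_config(),
                            candidate_gene = NULL,
                            tf_r_min = 0.6,
                            motif_threshold = 0.8,
                            motif_pseudocount = 1,
                            kmeans_k = NULL,
                            seed = 1L) {
  generator$seed <- as.integer(seed)
  structure(list(generator = generator, screen = screen,
                 candidate_gene = candidate_gene, tf_r_min = tf_r_min,
                 motif_threshold = motif_threshold,
                 motif_pseudocount = motif_pseudocount,
                 kmeans_k = kmeans_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Bundled synthetic GATA-like motif
#'
#' Loads the synthetic GATA-family-like position frequency matrix shipped
#' with the package (a WGATAA-core motif written for simulation, not a
#' database matrix).
#'
#' @return A [pfm()] object.
#' @export
gata_like_pfm <- function() {
  read_jaspar_pfm(system.file("extdata", "gata_like_synthetic.pfm",
                              package = "epimarker", mustWork = TRUE))
}

#' Run the full pipeline on a synthetic dataset
#'
#' Simulates expression data and promoters, runs the surface-marker screen,
#' the TF prioritization against the candidate promoter, PCA, AGNES
#' clustering and k-means, writes all artifacts under `out_dir` and a
#' `manifest.json` with md5 checksums. Rerunning with the same configuration
#' and seed reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return A `pipeline_result` list with components `sim`, `screen`, `tf`,
#'   `pca`, `tree`, `kmeans`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("epirun")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_expression(config$generator)
  scr <- run_screen(sim$expr, sim$design, sim$annotation, config$screen)

  norm <- normalize_expression(sim$expr, "cpm")
  logexpr <- log_transform(norm, 1)

  candidate <- config$candidate_gene %||%
    (if (length(scr$candidates) > 0) scr$candidates[[1]] else
       sim$truth$planted_marker_ids[[1]])

  # TF prioritization: candidate-correlated DEGs -> TFs -> promoter scan
  cds <- correlated_deg_set(logexpr, scr$deg, candidate, config$tf_r_min)
  tfs <- tf_intersection(cds$gene, sim$annotation)
  planted_pfm <- gata_like_pfm()
  planted_pfm$name <- "GATA4"
  set.seed(sub_seed(config$seed, 21))
  motif_library <- c(
    setNames(list(planted_pfm), "GATA4"),
    setNames(lapply(setdiff(sim$truth$tf_ids, "GATA4"), function(tf) {
      random_pfm(width = 8, id = paste0("SYN_", tf), name = tf)
    }), setdiff(sim$truth$tf_ids, "GATA4"))
  )
  prom <- simulate_promoters(config$generator, planted_pfm,
                             target_ids = candidate,
                             decoy_ids = paste0("decoy_", seq_len(5)))
  ranking <- prioritize_tfs(tfs, motif_library, prom$seqs[[candidate]],
                            threshold = config$motif_threshold,
                            pseudocount = config$motif_pseudocount)
  scan_pwm <- build_pwm(planted_pfm, config$motif_pseudocount)
  hits <- scan_promoter(scan_pwm, prom$seqs[[candidate]],
                        threshold = config$motif_threshold,
                        promoter_id = candidate)

  pca <- pca_samples(logexpr, sim$design)
  tree <- agnes_cluster(manhattan_distances(logexpr), "average")
  k <- config$kmeans_k %||% nlevels(sim$design$stage)
  km <- kmeans_samples(logexpr, k, seed = sub_seed(config$seed, 22))

  # write artifacts
  paths <- c(
    expression = write_expression_tsv(sim$expr, file.path(out_dir, "expression.tsv")),
    design = write_design_tsv(sim$design, file.path(out_dir, "design.tsv")),
    annotation = write_annotation_tsv(sim$annotation, file.path(out_dir, "annotation.tsv")),
    ledger = {
      readr::write_tsv(scr$ledger, file.path(out_dir, "screen_ledger.tsv"),
                       progress = FALSE)
      file.path(out_dir, "screen_ledger.tsv")
    },
    candidates = {
      readr::write_tsv(tibble(gene = scr$candidates),
                       file.path(out_dir, "candidates.tsv"), progress = FALSE)
      file.path(out_dir, "candidates.tsv")
    },
    deg = {
      readr::write_tsv(scr$deg, file.path(out_dir, "deg.tsv"), progress = FALSE)
      file.path(out_dir, "deg.tsv")
    },
    promoters = write_fasta(prom$seqs, file.path(out_dir, "promoters.fasta")),
    hits = write_hits_bed(hits, file.path(out_dir, "promoter_hits.bed")),
    tf_ranking = {
      readr::write_tsv(ranking, file.path(out_dir, "tf_ranking.tsv"),
                       progress = FALSE)
      file.path(out_dir, "tf_ranking.tsv")
    },
    pca_scores = {
      out <- tidy(pca); out$stage <- as.character(out$stage)
      readr::write_tsv(out, file.path(out_dir, "pca_scores.tsv"), progress = FALSE)
      file.path(out_dir, "pca_scores.tsv")
    },
    dendrogram = write_newick(tree, file.path(out_dir, "dendrogram.nwk")),
    kmeans = {
      readr::write_tsv(km$assignment, file.path(out_dir, "kmeans.tsv"),
                       progress = FALSE)
      file.path(out_dir, "kmeans.tsv")
    }
  )

  top_tf <- if (nrow(ranking) > 0) ranking$tf[[1]] else NA_character_
  summary <- list(
    candidates = scr$candidates,
    stage_counts = as.list(scr$stage_counts),
    candidate_gene = candidate,
    n_correlated_degs = nrow(cds),
    n_tfs = length(tfs),
    top_tf = top_tf,
    top_tf_score = if (nrow(ranking) > 0) ranking$best_rel_score[[1]] else NA_real_,
    pc1_var_explained = pca$var_explained[[1]],
    seed = config$seed
  )
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("epimarker")),
    files = lapply(paths, function(p) list(path = basename(p),
                                           md5 = unname(tools::md5sum(p)))),
    summary = summary
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(sim = sim, screen = scr, tf = ranking, correlated_degs = cds,
                 promoters = prom, hits = hits, pca = pca, tree = tree,
                 kmeans = km, summary = summary, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("epimarker pipeline run (seed ", x$summary$seed, ")\n", sep = "")
  cat("  candidates: ",
      if (length(x$summary$candidates)) paste(x$summary$candidates, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  top TF for ", x$summary$candidate_gene, ": ", x$summary$top_tf,
      " (relative score ", sprintf("%.3f", x$summary$top_tf_score), ")\n", sep = "")
  cat("  PC1 variance explained: ",
      sprintf("%.1f%%", 100 * x$summary$pc1_var_explained), "\n", sep = "")
  cat("  outputs: ", x$out_dir, "\n", sep = "")
  invisible(x)
}
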