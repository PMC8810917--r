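# Synthetic staged expression data with planted ground truth. The generator
# emulates a three-stage developmental design (early and late active
# epicardium, adult quiescent epicardium): anchor genes rise monotonically
# from early to late and are silenced in the adult stage; planted surface
# markers share the anchors' latent trajectory with calibrated noise so their
# sample-wise Pearson correlation to the anchors approaches a configured
# target; endothelial genes follow the reversed trajectory; background genes
# carry no structure. Counts are gamma-Poisson around the latent means with
# per-sample library-size scaling.

#' Generator configuration
#'
#' @param n_background_genes Unstructured genes.
#' @param n_planted_markers Surface-marker genes planted on the anchor
#'   trajectory.
#' @param n_endothelial_genes Genes on the reversed (anti-correlated)
#'   trajectory beyond the two named endothelial anchors.
#' @param n_regulator_tfs Transcription-factor genes planted on the anchor
#'   trajectory (upstream-regulator candidates); the first is named `GATA4`.
#' @param n_adult_persistent Control genes matching the anchors at early/late
#'   but persisting at the late-stage level in adult samples.
#' @param anchor_names,endothelial_anchor_names Anchor gene identifiers.
#' @param stages Named integer vector: replicates per ordered stage.
#' @param anchor_trajectory Named numeric vector: per-stage mean expression
#'   (count scale) for anchors; monotone increasing early to late, near zero
#'   in adult (default adult mean is 1% of the late mean).
#' @param target_marker_correlation Pearson target in (0, 1] for planted
#'   markers against anchors, on the log2(cpm + 1) scale.
#' @param anchor_noise_sd,background_noise_sd Log2-scale biological noise.
#' @param background_log2_mean,background_log2_sd Distribution of background
#'   gene baselines (log2 count scale).
#' @param surface_background_fraction Fraction of background genes flagged as
#'   surface (screen decoys).
#' @param tf_background_fraction Fraction of background genes flagged as
#'   transcription factors (regulator decoys).
#' @param dispersion Gamma-Poisson overdispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param library_size_mean,library_size_cv Per-sample scaling factor
#'   distribution (log-normal).
#' @param promoter_length Promoter length in bases.
#' @param planted_motif_offset 0-based start position of the planted motif
#'   instance within target promoters; `NULL` places it 100 bases before the
#'   sequence end (near the transcription start site).
#' @param seed Master seed; sub-streams are derived per component.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_background_genes = 2000,
                       n_planted_markers = 10,
                       n_endothelial_genes = 10,
                       n_regulator_tfs = 5,
                       n_adult_persistent = 0,
                       anchor_names = c("WT1", "TBX18", "ALDH1A2"),
                       endothelial_anchor_names = c("CDH5", "PECAM1"),
                       stages = c(early = 4, late = 4, adult = 4),
                       anchor_trajectory = c(early = 50, late = 500, adult = 5),
                       target_marker_correlation = 0.9,
                       anchor_noise_sd = 0.15,
                       background_noise_sd = 0.5,
                       background_log2_mean = 6,
                       background_log2_sd = 1.5,
                       surface_background_fraction = 0.05,
                       tf_background_fraction = 0.01,
                       dispersion = 0.05,
                       library_size_mean = 1,
                       library_size_cv = 0.1,
                       promoter_length = 1000,
                       planted_motif_offset = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (n_background_genes < 0 || n_planted_markers < 0 ||
      n_endothelial_genes < 0) {
    abort("gene counts must be non-negative")
  }
  if (target_marker_correlation <= 0 || target_marker_correlation > 1) {
    abort("target_marker_correlation must be in (0, 1]")
  }
  if (is.null(names(stages)) || any(stages < 1)) {
    abort("stages must be a named vector of positive replicate counts")
  }
  if (!identical(sort(names(stages)), sort(names(anchor_trajectory)))) {
    abort("anchor_trajectory must name the same stages as `stages`")
  }
  pools <- c(anchor_names, endothelial_anchor_names)
  if (anyDuplicated(pools)) abort("gene-name pools must be disjoint")
  structure(cfg, class = "sim_config")
}

# derive a reproducible sub-seed for a named component
sub_seed <- function(seed, offset) as.integer((as.numeric(seed) * 31 + offset) %% 2147483647)

# gamma-Poisson counts around per-sample means `mu` (count scale)
gp_counts <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion <= 0) return(rpois(n, mu))
  shape <- 1 / dispersion
  rpois(n, rgamma(n, shape = shape, rate = shape) * mu)
}

# log2-scale count-noise variance at stage mean `mu`, evaluated on the
# normalized log2(cpm + 1) scale the screen correlates on. A delta-method
# formula (var ~ (1/mu + disp) / ln(2)^2) underestimates badly at low means
# (zero counts land far below the trajectory after the log), so the variance
# is measured by Monte Carlo on the actual gamma-Poisson model; `cpm_factor`
# is the expected counts-to-cpm scaling. Uses the current RNG stream.
count_log2_var <- function(mu, dispersion, cpm_factor, n_mc = 4000) {
  vapply(mu, function(m) {
    x <- gp_counts(rep(m, n_mc), dispersion)
    var(log2(cpm_factor * x + 1))
  }, 0)
}

#' Generate a synthetic staged expression dataset
#'
#' @param config A [sim_config()].
#' @return An object of class `epi_sim`: list with `expr` (expression
#'   tibble), `design` (stage design), `annotation` (gene annotation),
#'   `truth` (planted identities and parameters) and `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  stage_names <- names(cfg$stages)
  n_per <- as.integer(cfg$stages)
  samples <- unlist(lapply(seq_along(stage_names), function(i) {
    paste0(stage_names[i], "_", seq_len(n_per[i]))
  }))
  stage_of <- rep(stage_names, times = n_per)
  n_s <- length(samples)
  design <- stage_design(samples, stage_of, stage_levels = stage_names)

  traj_counts <- cfg$anchor_trajectory[stage_of]
  traj_log2 <- log2(traj_counts)
  V <- var(traj_log2)

  # noise calibration: markers share the latent trajectory; the marker noise
  # variance is solved in closed form from the correlation target, with a
  # Monte-Carlo allowance for downstream count noise on both sides
  expected_total <- mean(cfg$anchor_trajectory) *
      (length(cfg$anchor_names) + length(cfg$endothelial_anchor_names) +
         cfg$n_planted_markers + cfg$n_endothelial_genes +
         cfg$n_regulator_tfs + cfg$n_adult_persistent) +
    cfg$n_background_genes *
      2^(cfg$background_log2_mean + (cfg$background_log2_sd * log(2))^2 / 2 +
           (cfg$background_noise_sd * log(2))^2 / 2)
  cpm_factor <- 1e6 / max(expected_total, 1)
  set.seed(sub_seed(cfg$seed, 9))
  vc <- mean(count_log2_var(traj_counts, cfg$dispersion, cpm_factor))
  va_eff <- cfg$anchor_noise_sd^2 + vc
  rho <- cfg$target_marker_correlation
  vm_total <- V^2 / (rho^2 * (V + va_eff)) - V
  marker_sd <- sqrt(max(0, vm_total - vc))

  set.seed(sub_seed(cfg$seed, 1))
  lib <- rlnorm(n_s, meanlog = log(cfg$library_size_mean) -
                  log(1 + cfg$library_size_cv^2) / 2,
                sdlog = sqrt(log(1 + cfg$library_size_cv^2)))

  gene_block <- function(ids, mu_log2_rows, noise_sd, seed_offset) {
    if (length(ids) == 0) {
      return(matrix(0, 0, n_s, dimnames = list(character(), samples)))
    }
    set.seed(sub_seed(cfg$seed, seed_offset))
    out <- matrix(0, length(ids), n_s, dimnames = list(ids, samples))
    for (i in seq_along(ids)) {
      mu_log2 <- mu_log2_rows[i, ] + rnorm(n_s, 0, noise_sd)
      out[i, ] <- gp_counts(lib * 2^mu_log2, cfg$dispersion)
    }
    out
  }
  rep_rows <- function(v, k) matrix(rep(v, each = k), nrow = k, byrow = FALSE)

  anchors <- cfg$anchor_names
  endo_anchors <- cfg$endothelial_anchor_names
  markers <- sprintf("MKR%02d", seq_len(cfg$n_planted_markers))
  endo_extra <- sprintf("END%02d", seq_len(cfg$n_endothelial_genes))
  regulators <- if (cfg$n_regulator_tfs > 0) {
    c("GATA4", sprintf("RTF%02d", seq_len(cfg$n_regulator_tfs))[-1])
  } else character()
  persistent <- sprintf("PERS%02d", seq_len(cfg$n_adult_persistent))
  background <- sprintf("BG%05d", seq_len(cfg$n_background_genes))

  traj_rev <- (max(traj_log2) + min(traj_log2)) - traj_log2
  late_level <- log2(cfg$anchor_trajectory[["late"]])
  traj_persist <- ifelse(stage_of == "adult", late_level, traj_log2)

  blocks <- list(
    gene_block(anchors, rep_rows(traj_log2, length(anchors)),
               cfg$anchor_noise_sd, 2),
    gene_block(c(endo_anchors, endo_extra),
               rep_rows(traj_rev, length(endo_anchors) + length(endo_extra)),
               cfg$anchor_noise_sd, 3),
    gene_block(markers, rep_rows(traj_log2, length(markers)), marker_sd, 4),
    gene_block(regulators, rep_rows(traj_log2, length(regulators)),
               marker_sd, 7),
    gene_block(persistent, rep_rows(traj_persist, length(persistent)),
               marker_sd, 8)
  )
  if (cfg$n_background_genes > 0) {
    set.seed(sub_seed(cfg$seed, 5))
    base <- rnorm(cfg$n_background_genes, cfg$background_log2_mean,
                  cfg$background_log2_sd)
    blocks <- c(blocks, list(gene_block(background, rep_rows(rep(0, n_s),
                  cfg$n_background_genes) + base, cfg$background_noise_sd, 5)))
  }
  mat <- do.call(rbind, blocks)

  set.seed(sub_seed(cfg$seed, 6))
  surf_bg <- sort(sample(background,
                         round(cfg$surface_background_fraction *
                                 length(background))))
  tf_bg <- sort(sample(setdiff(background, surf_bg),
                       round(cfg$tf_background_fraction * length(background))))
  annotation <- gene_annotation(
    gene = rownames(mat),
    is_surface = rownames(mat) %in% c(markers, persistent, surf_bg),
    is_tf = rownames(mat) %in% c(regulators, tf_bg),
    role = dplyr::case_when(
      rownames(mat) %in% anchors ~ "anchor_epicardial",
      rownames(mat) %in% endo_anchors ~ "anchor_endothelial",
      rownames(mat) %in% markers ~ "candidate",
      TRUE ~ "other"
    )
  )
  truth <- list(planted_marker_ids = markers,
                endothelial_ids = c(endo_anchors, endo_extra),
                anchor_ids = anchors,
                tf_ids = regulators,
                persistent_ids = persistent,
                decoy_surface_ids = surf_bg,
                decoy_tf_ids = tf_bg,
                motif_positions = tibble(promoter = character(),
                                         start = integer(),
                                         strand = character()),
                generator_seed = cfg$seed)
  structure(list(expr = expression_table(mat), design = design,
                 annotation = annotation, truth = truth, config = cfg),
            class = "epi_sim")
}

#' Generate synthetic promoter sequences with a planted motif
#'
#' Target promoters carry one motif instance (the consensus by default, or a
#' base-wise sample from the frequency matrix) at a configured offset on a
#' random strand; decoy promoters are i.i.d. uniform bases. The returned
#' truth records exact positions and strands.
#'
#' @param config A [sim_config()] (uses `promoter_length`,
#'   `planted_motif_offset`, `seed`).
#' @param pfm A [pfm()] motif to plant.
#' @param target_ids Promoter ids receiving a planted instance.
#' @param decoy_ids Promoter ids left unstructured.
#' @param sample_instance If `TRUE`, draw the planted instance base-wise from
#'   the column frequencies instead of using the consensus.
#' @return List with `seqs` (named character vector) and `motif_positions`
#'   (tibble: promoter, start, strand).
#' @export
simulate_promoters <- function(config, pfm, target_ids = character(),
                               decoy_ids = character(),
                               sample_instance = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(pfm, "pfm"))
  L <- ncol(pfm$counts)
  plen <- config$promoter_length
  if (plen < L) abort("motif longer than promoter")
  offset <- config$planted_motif_offset %||% max(0L, plen - 100L - L)
  if (offset + L > plen) abort("planted motif does not fit at this offset")
  set.seed(sub_seed(config$seed, 11))
  bases <- c("A", "C", "G", "T")
  draw <- function() paste(sample(bases, plen, replace = TRUE), collapse = "")
  ids <- c(target_ids, decoy_ids)
  if (anyDuplicated(ids)) abort("duplicate promoter ids")
  seqs <- vapply(ids, function(i) draw(), "")
  positions <- tibble(promoter = character(), start = integer(),
                      strand = character())
  for (id in target_ids) {
    inst <- if (sample_instance) {
      probs <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
      paste(vapply(seq_len(L), function(j) sample(bases, 1, prob = probs[, j]),
                   ""), collapse = "")
    } else pwm_consensus(build_pwm(pfm))
    strand <- sample(c("+", "-"), 1)
    planted <- if (strand == "+") inst else revcomp(inst)
    seq <- seqs[[id]]
    substr(seq, offset + 1L, offset + L) <- planted
    seqs[[id]] <- seq
    positions <- bind_rows(positions,
                           tibble(promoter = id, start = as.integer(offset),
                                  strand = strand))
  }
  list(seqs = seqs, motif_positions = positions)
}

#' Random decoy motif
#'
#' Draws a position frequency matrix with one dominant base per column, for
#' use as a decoy in prioritization experiments. Uses the current RNG stream.
#'
#' @param width Motif width.
#' @param id,name Motif identifiers.
#' @param total Counts per column.
#' @return A [pfm()] object.
#' @export
random_pfm <- function(width = 8, id = "decoy", name = id, total = 20) {
  counts <- sapply(seq_len(width), function(j) {
    dominant <- sample(4, 1)
    base <- rep(1, 4)
    base[dominant] <- total - 3
    base
  })
  pfm(counts, id = id, name = name)
}

#' @export
print.epi_sim <- function(x, ...) {
  cat("Synthetic staged expression dataset\n")
  cat("  genes:  ", nrow(x$expr), "  samples: ", nrow(x$design), "\n", sep = "")
  cat("  stages: ",
      paste(levels(x$design$stage), table(x$design$stage)[levels(x$design$stage)],
            sep = ":", collapse = "  "), "\n", sep = "")
  cat("  planted markers: ", length(x$truth$planted_marker_ids),
      "; regulator TFs: ", length(x$truth$tf_ids), "\n", sep = "")
  invisible(x)
}
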