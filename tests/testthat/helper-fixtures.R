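# Small fixtures built in code.

# compact generator configuration for fast tests; dots override defaults
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(n_background_genes = 120, n_planted_markers = 5,
                   n_endothelial_genes = 4, n_regulator_tfs = 3, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# tiny hand-built staged dataset with clean structure: 2 anchors rising and
# silenced in adult, 1 endothelial anchor reversed, marker tracking anchors,
# one flat background gene, one adult-persistent gene
toy_staged_dataset <- function() {
  samples <- c(paste0("early_", 1:3), paste0("late_", 1:3), paste0("adult_", 1:3))
  design <- stage_design(samples, rep(c("early", "late", "adult"), each = 3))
  mat <- rbind(
    WT1     = c(10, 12, 11, 100, 110, 105, 0, 1, 0),
    TBX18   = c(11, 10, 12, 108, 102, 101, 1, 0, 1),
    ALDH1A2 = c(9, 11, 10, 99, 104, 108, 0, 0, 1),
    CDH5    = c(50, 52, 49, 5, 6, 4, 100, 104, 99),
    PECAM1  = c(48, 51, 50, 6, 4, 5, 102, 98, 100),
    MKRA    = c(12, 13, 11, 95, 105, 100, 0, 1, 1),
    PERSA   = c(10, 12, 13, 101, 99, 104, 100, 102, 98),
    FLAT    = c(20, 21, 20, 20, 21, 20, 21, 20, 20)
  )
  colnames(mat) <- samples
  ann <- gene_annotation(rownames(mat),
                         is_surface = rownames(mat) %in% c("MKRA", "PERSA"),
                         is_tf = FALSE,
                         role = dplyr::case_when(
                           rownames(mat) %in% c("WT1", "TBX18", "ALDH1A2") ~
                             "anchor_epicardial",
                           rownames(mat) %in% c("CDH5", "PECAM1") ~
                             "anchor_endothelial",
                           TRUE ~ "other"))
  list(expr = expression_table(mat), design = design, annotation = ann)
}

toy_pfm <- function() {
  pfm(rbind(c(10, 0, 0, 8), c(0, 10, 1, 1), c(0, 0, 8, 1), c(0, 0, 1, 0)),
      id = "TOY1", name = "toy")
}

# 8-bp non-palindromic motif (consensus AAGATCCG) for planting tests, long
# enough that random sequence almost never contains the consensus by chance
plant_pfm <- function() {
  cons <- c("A", "A", "G", "A", "T", "C", "C", "G")
  counts <- sapply(cons, function(b) {
    v <- rep(0, 4); v[match(b, c("A", "C", "G", "T"))] <- 10; v
  })
  pfm(counts, id = "PLANT8", name = "plant")
}
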