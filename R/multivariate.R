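# Sample-structure analyses: PCA with variance-explained fractions and a
# deterministic sign convention; agglomerative clustering (AGNES) with
# Lance-Williams updates and a fixed tie-break, exportable as Newick; seeded
# Lloyd k-means with restarts.

#' PCA of samples from an expression table
#'
#' Samples are observations, genes variables. The matrix is gene-centered
#' (and optionally unit-scaled) before decomposition. Signs follow a fixed
#' convention: within each component the loading of largest magnitude is
#' positive.
#'
#' @param expr Expression tibble, typically log2(cpm + 1).
#' @param design Optional stage design joined onto the scores.
#' @param scale. Unit-scale genes before decomposition; default `FALSE`.
#' @return An `expr_pca` object: list with `scores` (tibble), `loadings`,
#'   `var_explained` (fractions, descending, summing to 1).
#' @export
pca_samples <- function(expr, design = NULL, scale. = FALSE) {
  m <- t(expr_matrix(validate_expression(expr)))
  if (nrow(m) < 2) abort("PCA needs at least 2 samples")
  if (scale.) {
    keep <- apply(m, 2, sd) > 0
    m <- m[, keep, drop = FALSE]
  }
  if (sum(apply(m, 2, var)) == 0) abort("degenerate input: zero total variance")
  fit <- prcomp(m, center = TRUE, scale. = scale.)
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x, rownames = "sample")
  if (!is.null(design)) scores <- left_join(scores, design, by = "sample")
  structure(list(scores = scores, loadings = fit$rotation,
                 var_explained = ve, sdev = fit$sdev),
            class = "expr_pca")
}

#' @export
print.expr_pca <- function(x, ...) {
  cat("Sample PCA: ", nrow(x$scores), " samples, ",
      length(x$var_explained), " components\n", sep = "")
  cat("  variance explained: ",
      paste0(sprintf("PC%d=%.1f%%", seq_len(min(3, length(x$var_explained))),
                     100 * x$var_explained[seq_len(min(3, length(x$var_explained)))]),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn pca_samples Sample scores as a tibble.
#' @param x An `expr_pca` object.
#' @param ... Unused.
#' @export
tidy.expr_pca <- function(x, ...) x$scores

#' @describeIn pca_samples One row per component with variance fractions.
#' @export
glance.expr_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_explained)),
         sdev = x$sdev, var_explained = x$var_explained,
         cum_var_explained = cumsum(x$var_explained))
}

#' @describeIn pca_samples Score scatter on the first two components,
#'   colored by stage when available.
#' @param object An `expr_pca` object.
#' @export
autoplot.expr_pca <- function(object, ...) {
  df <- object$scores
  ve <- object$var_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
                  title = "Sample PCA") +
    ggplot2::theme_minimal()
  if ("stage" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$stage), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
}

#' Manhattan (city-block) distances between samples
#'
#' @param expr Expression tibble.
#' @return Symmetric distance matrix with sample names.
#' @export
manhattan_distances <- function(expr) {
  m <- t(expr_matrix(validate_expression(expr)))
  as.matrix(stats::dist(m, method = "manhattan"))
}

#' Agglomerative hierarchical clustering (AGNES)
#'
#' Bottom-up merging of the nearest cluster pair with Lance-Williams
#' dissimilarity updates for the chosen linkage. Ties are broken by the
#' smallest (i, j) index pair, making the merge history deterministic.
#'
#' @param distances Square symmetric distance matrix (e.g. from
#'   [manhattan_distances()]).
#' @param linkage One of `"average"` (default), `"single"`, `"complete"`.
#' @return A `merge_tree`: list with `merge` (hclust-style), `height`,
#'   `labels`, `linkage`.
#' @export
agnes_cluster <- function(distances, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    abort("distances must be a square symmetric matrix")
  }
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  if (n < 2) abort("need at least 2 samples to cluster")
  diag(d) <- Inf
  # active cluster bookkeeping: id < 0 -> leaf, id > 0 -> merge row
  id <- -seq_len(n)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    # smallest (i, j) with i < j in original index order
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- idx[best[1]]; j <- idx[best[2]]
    h <- d[i, j]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- h
    # Lance-Williams update of distances from the merged cluster to the rest
    others <- idx[idx != i & idx != j]
    for (k in others) {
      dik <- d[i, k]; djk <- d[j, k]
      d[i, k] <- d[k, i] <- switch(linkage,
        single = min(dik, djk),
        complete = max(dik, djk),
        average = (size[i] * dik + size[j] * djk) / (size[i] + size[j]))
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage),
            class = "merge_tree")
}

#' Convert a merge tree to an hclust object
#'
#' @param tree A `merge_tree`.
#' @return A `stats::hclust` object (usable with [ape::as.phylo()]).
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  structure(list(merge = tree$merge, height = tree$height,
                 order = hclust_order(tree$merge), labels = tree$labels,
                 method = tree$linkage, call = match.call(),
                 dist.method = "manhattan"),
            class = "hclust")
}

# leaf ordering by depth-first traversal of the merge history
hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Seeded k-means of samples
#'
#' Lloyd iterations from random initial centers, best of `n_init` restarts by
#' within-cluster sum of squares; deterministic given the seed.
#'
#' @param expr Expression tibble.
#' @param k Number of clusters, `1 <= k <=` number of samples.
#' @param seed RNG seed.
#' @param n_init Number of restarts; default 10.
#' @return List with `assignment` (tibble sample/cluster) and `inertia`.
#' @export
kmeans_samples <- function(expr, k, seed = 1L, n_init = 10) {
  m <- t(expr_matrix(validate_expression(expr)))
  if (k > nrow(m)) abort("k must not exceed the number of samples")
  if (k < 1) abort("k must be at least 1")
  set.seed(seed)
  fit <- suppressWarnings(
    kmeans(m, centers = k, nstart = n_init, algorithm = "Lloyd",
           iter.max = 100)
  )
  list(assignment = tibble(sample = rownames(m),
                           cluster = unname(fit$cluster)),
       inertia = fit$tot.withinss)
}
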