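# Arithmetic substrate of the screen: normalization, log transform, Pearson
# correlation with t-based significance, stage fold change, least squares.

#' Normalize an expression table
#'
#' `cpm` scales each sample column to one million total. `upper_quartile`
#' divides each column by its 75th percentile over genes with nonzero values,
#' then rescales so the global mean upper quartile is preserved. `none` is the
#' identity.
#'
#' @param expr Expression tibble.
#' @param method One of `"cpm"`, `"upper_quartile"`, `"none"`.
#' @return Normalized expression tibble, same shape and ordering.
#' @export
normalize_expression <- function(expr, method = c("cpm", "upper_quartile", "none")) {
  method <- match.arg(method)
  expr <- validate_expression(expr)
  if (method == "none") return(expr)
  m <- expr_matrix(expr)
  if (method == "cpm") {
    totals <- colSums(m)
    if (any(totals == 0)) {
      abort(paste0("all-zero sample column(s): ",
                   paste(colnames(m)[totals == 0], collapse = ", ")))
    }
    m <- sweep(m, 2, totals, "/") * 1e6
  } else {
    uq <- apply(m, 2, function(col) {
      nz <- col[col > 0]
      if (length(nz) == 0) abort("all-zero sample column under upper_quartile")
      quantile(nz, 0.75, names = FALSE)
    })
    m <- sweep(m, 2, uq, "/") * mean(uq)
  }
  expression_table(m)
}

#' Log2 transform with pseudocount
#'
#' @param expr Expression tibble.
#' @param pseudocount Added before the log; default 1.
#' @return Transformed tibble.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  m <- expr_matrix(validate_expression(expr))
  expression_table(log2(m + pseudocount))
}

#' Pearson correlation with two-sided significance
#'
#' r by the product-moment formula; p from the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against a Student t with n - 2
#' degrees of freedom, two-sided. Perfect correlation returns p = 0. A
#' constant vector is an error (the caller excludes such genes, with a
#' warning).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A one-row tibble with columns `r`, `n`, `p`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("undefined correlation: constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1 - 1e-15) 0 else unname(ct$p.value)
  tibble(r = r, n = length(x), p = p)
}

# Correlation of every gene row against each anchor row, on the matrix scale
# supplied. Constant genes get NA r/p and a single collected warning. Returns
# long tibble (gene, anchor, r, n, p).
correlate_to_anchors <- function(m, anchor_ids) {
  missing <- setdiff(anchor_ids, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("anchor gene(s) absent from matrix: ",
                 paste(missing, collapse = ", ")))
  }
  n <- ncol(m)
  sds <- apply(m, 1, sd)
  if (any(sds[anchor_ids] == 0)) {
    abort(paste0("constant anchor gene(s): ",
                 paste(anchor_ids[sds[anchor_ids] == 0], collapse = ", ")))
  }
  const <- sds == 0
  if (any(const)) {
    warn(paste0(sum(const), " constant gene(s) excluded from correlation"))
  }
  rmat <- suppressWarnings(cor(t(m), t(m[anchor_ids, , drop = FALSE])))
  rmat[const, ] <- NA_real_
  rmat[rmat > 1] <- 1; rmat[rmat < -1] <- -1
  tstat <- rmat * sqrt(n - 2) / sqrt(pmax(1 - rmat^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rmat) >= 1 - 1e-15] <- 0
  tibble(gene = rep(rownames(m), times = length(anchor_ids)),
         anchor = rep(anchor_ids, each = nrow(m)),
         r = as.vector(rmat), n = n, p = as.vector(p))
}

#' Stage fold change per gene
#'
#' Arithmetic stage means on the supplied (normalized) scale;
#' `fc = (mean_to + c) / (mean_from + c)` with pseudocount `c`.
#'
#' @param expr Expression tibble (normalized scale).
#' @param design Stage design tibble.
#' @param from_stage,to_stage Stage labels; fold change is `to` over `from`.
#' @param pseudocount Non-negative; default 1.
#' @return Tibble (gene, mean_early, mean_late, fc, log2fc) where the mean
#'   columns refer to `from_stage` and `to_stage` respectively.
#' @export
fold_change <- function(expr, design, from_stage = "early", to_stage = "late",
                        pseudocount = 1) {
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  check_design_matches(expr, design)
  m <- expr_matrix(expr)
  s_from <- stage_samples(design, from_stage)
  s_to <- stage_samples(design, to_stage)
  mean_from <- rowMeans(m[, s_from, drop = FALSE])
  mean_to <- rowMeans(m[, s_to, drop = FALSE])
  fc <- (mean_to + pseudocount) / (mean_from + pseudocount)
  tibble(gene = rownames(m), mean_early = unname(mean_from),
         mean_late = unname(mean_to), fc = unname(fc),
         log2fc = log2(unname(fc)))
}

#' Ordinary least squares line through paired measurements
#'
#' Used for co-expression of a candidate marker and its putative regulator
#' across induction time points.
#'
#' @param x,y Numeric vectors, n >= 2; x non-constant.
#' @return One-row tibble (slope, intercept, r).
#' @export
regression_line <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 points")
  if (sd(x) == 0) abort("constant x: regression undefined")
  if (sd(y) == 0) abort("undefined correlation: constant vector")
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- pearson_test(x, y)$r
  tibble(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]), r = r)
}
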