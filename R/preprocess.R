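#' Convert raw counts to log2 RPKM
#'
#' RPKM = 10^9 * count / (gene length in bp * library size); values are
#' returned as `log2(RPKM + pseudocount)`. The pseudocount defaults to 1 so
#' zero counts map to exactly 0.
#'
#' @param counts Non-negative integer genes x samples count matrix.
#' @param gene_lengths Named vector of gene lengths in base pairs (or a
#'   two-column data frame `gene_id`, `length_bp`), covering all genes.
#' @param pseudocount Added inside the log2.
#'
#' @return A genes x samples matrix on the log2 RPKM scale.
#' @export
#' @examples
#' m <- matrix(c(1000, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' rpkm_log2(m + c(0, 999000 - 1000), setNames(c(1000, 1000), c("g1", "g2")))
rpkm_log2 <- function(counts, gene_lengths, pseudocount = 1) {
  check_expr(counts, "counts")
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths[[2]], gene_lengths[[1]])
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing)) {
    abort(sprintf("gene lengths missing for: %s", paste(head(missing, 5), collapse = ", ")))
  }
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) abort("gene lengths must be positive")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort(sprintf("zero library size for sample(s): %s",
                  paste(colnames(counts)[lib == 0], collapse = ", ")))
  }
  rpkm <- sweep(counts / len, 2L, lib, "/") * 1e9
  out <- log2(rpkm + pseudocount)
  attr(out, "scale_tag") <- "rpkm_log2"
  out
}

#' Filter genes by mean expression and variability
#'
#' Retains genes with row mean above `mean_min` and raw median absolute
#' deviation (median of absolute deviations from the row median, no
#' consistency factor unless `scaled_mad`) above `mad_min` — the retention
#' rule used ahead of subtype discovery.
#'
#' @param expr log2-scale genes x samples matrix.
#' @param mean_min Row-mean threshold (log2 units).
#' @param mad_min Row-MAD threshold.
#' @param scaled_mad Use the 1.4826-scaled MAD instead of the raw statistic.
#'
#' @return The filtered matrix.
#' @export
filter_genes <- function(expr, mean_min = 1, mad_min = 0.5, scaled_mad = FALSE) {
  check_expr(expr)
  keep <- rowMeans(expr) > mean_min & row_mads(expr, scaled = scaled_mad) > mad_min
  if (!any(keep)) warn("no genes pass the expression filter")
  expr[keep, , drop = FALSE]
}

#' Median-center each gene
#'
#' Subtracts the per-gene median so every row has median 0. Idempotent.
#'
#' @param expr log2-scale genes x samples matrix.
#' @return The centered matrix (scale tag `centered`).
#' @export
median_center <- function(expr) {
  check_expr(expr)
  out <- expr - apply(expr, 1L, median)
  attr(out, "scale_tag") <- "centered"
  out
}

#' Remove batch effects with parametric empirical-Bayes adjustment
#'
#' Per-gene location-scale batch adjustment with empirical-Bayes shrinkage of
#' the batch parameters (ComBat). A single batch returns the input unchanged;
#' a batch with fewer than 2 samples is an error because its scale is
#' undefined.
#'
#' @param expr log2-scale genes x samples matrix.
#' @param batches Per-sample batch labels (named vector or in column order).
#' @return The adjusted matrix, same dimensions.
#' @export
batch_correct <- function(expr, batches) {
  check_expr(expr)
  if (!is.null(names(batches))) {
    if (!setequal(names(batches), colnames(expr))) {
      abort("`batches` names must match the expression samples")
    }
    batches <- batches[colnames(expr)]
  }
  if (length(batches) != ncol(expr)) {
    abort("`batches` must have one entry per sample")
  }
  batches <- as.character(batches)
  tab <- table(batches)
  if (any(tab < 2)) {
    abort(sprintf("batch '%s' has fewer than 2 samples; scale is undefined",
                  names(tab)[tab < 2][1]))
  }
  if (length(tab) < 2) {
    return(expr)
  }
  # ComBat drops zero-variance genes internally; guard by jittering constant
  # rows is not acceptable, so handle them explicitly: constant genes are
  # passed through unchanged.
  constant <- apply(expr, 1L, function(x) var(x) == 0)
  out <- expr
  if (any(!constant)) {
    adj <- suppressMessages(
      sva::ComBat(dat = expr[!constant, , drop = FALSE], batch = batches)
    )
    out[!constant, ] <- adj
  }
  attr(out, "scale_tag") <- attr(expr, "scale_tag")
  out
}

#' Principal-component scores of samples
#'
#' Scores of the column-centered data (samples as observations, genes as
#' variables) on the leading right singular directions; used to inspect batch
#' structure.
#'
#' @param expr genes x samples matrix.
#' @param n_components Number of components to return.
#' @return A tibble `sample_id`, `PC1`, ..., plus attribute
#'   `explained_variance` (per-component fraction).
#' @export
pca_scores <- function(expr, n_components = 2L) {
  check_expr(expr)
  if (ncol(expr) < 2) abort("need at least 2 samples")
  n_components <- min(n_components, ncol(expr) - 1L, nrow(expr))
  fit <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  out <- as_tibble(scores)
  out <- dplyr::bind_cols(tibble(sample_id = colnames(expr)), out)
  attr(out, "explained_variance") <- fit$sdev^2 / sum(fit$sdev^2)
  out
}
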