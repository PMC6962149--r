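# Unsupervised subtype discovery: agglomerative clustering, consensus
# clustering with stability curves, and the gap statistic for choosing k.

# Pairwise sample distances for a genes x samples matrix.
sample_distance <- function(expr, distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  if (distance == "pearson") {
    as.dist(1 - cor(expr))
  } else {
    dist(t(expr))
  }
}

#' Agglomerative hierarchical clustering of samples
#'
#' Average-linkage agglomerative clustering on 1 - Pearson correlation
#' between sample columns (Euclidean distance optional), cut at `k` groups.
#' Deterministic for identical input.
#'
#' @param expr genes x samples matrix (log scale or centered).
#' @param k Number of clusters.
#' @param linkage Agglomeration method (passed to [stats::hclust()]).
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#'
#' @return A tibble `sample_id`, `label` with labels `C1..Ck` numbered by
#'   first appearance in column order.
#' @export
hierarchical_cluster <- function(expr, k, linkage = "average",
                                 distance = c("pearson", "euclidean")) {
  check_expr(expr)
  if (k > ncol(expr)) abort("k exceeds the number of samples")
  d <- sample_distance(expr, distance)
  cl <- cutree(hclust(d, method = linkage), k = k)
  tibble(sample_id = colnames(expr), label = paste0("C", unname(cl)))
}

#' Consensus clustering over subsampled replicates
#'
#' Repeatedly subsamples `ceiling(subsample * n)` samples without
#' replacement, clusters each subsample with [hierarchical_cluster()], and
#' records for every sample pair how often it co-clusters among the
#' iterations where it was co-sampled. Final labels come from average-linkage
#' clustering of `1 - consensus`.
#'
#' @param expr genes x samples matrix.
#' @param k_range Cluster numbers to evaluate (within `[2, n - 1]`).
#' @param iterations Number of subsampling iterations.
#' @param subsample Fraction of samples drawn each iteration.
#' @param seed Integer seed.
#' @inheritParams hierarchical_cluster
#'
#' @return A named list (`"k=2"`, ...) of `consensus_result` objects, each
#'   with fields `k`, `consensus` (samples x samples matrix in \[0, 1\] with
#'   unit diagonal), `labels` (tibble), `iterations`, `subsample_fraction`.
#' @export
consensus_cluster <- function(expr, k_range = 2:6, iterations = 1000,
                              subsample = 0.95, seed = 1L,
                              linkage = "average",
                              distance = c("pearson", "euclidean")) {
  check_expr(expr)
  n <- ncol(expr)
  if (any(k_range < 2) || any(k_range > n - 1)) {
    abort("k_range must lie within [2, n - 1]")
  }
  distance <- match.arg(distance)
  m <- ceiling(subsample * n)
  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_clustered) <- as.character(k_range)

  with_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- if (m >= n) seq_len(n) else sort(sample.int(n, m))
      sub <- expr[, idx, drop = FALSE]
      d <- sample_distance(sub, distance)
      tree <- hclust(d, method = linkage)
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      for (k in k_range) {
        cl <- cutree(tree, k = k)
        same <- outer(cl, cl, "==")
        kk <- as.character(k)
        co_clustered[[kk]][idx, idx] <- co_clustered[[kk]][idx, idx] + same
      }
    }
  })

  never <- co_sampled == 0 & upper.tri(co_sampled)
  if (any(never)) {
    warn(sprintf("%d sample pair(s) were never co-sampled; consensus set to 0",
                 sum(never)))
  }
  out <- lapply(k_range, function(k) {
    cons <- co_clustered[[as.character(k)]] / co_sampled
    cons[co_sampled == 0] <- 0
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(expr), colnames(expr))
    lab <- cutree(hclust(as.dist(1 - cons), method = linkage), k = k)
    structure(
      list(
        k = k,
        consensus = cons,
        labels = tibble(sample_id = colnames(expr), label = paste0("C", unname(lab))),
        iterations = iterations,
        subsample_fraction = subsample
      ),
      class = "consensus_result"
    )
  })
  names(out) <- paste0("k=", k_range)
  out
}

#' Empirical CDF of consensus values
#'
#' The empirical distribution of the off-diagonal consensus entries; the
#' flatter the middle of this CDF, the more binary (stable) the clustering.
#'
#' @param result A `consensus_result`.
#' @return A tibble `value`, `cdf` over the sorted off-diagonal entries.
#' @export
consensus_cdf <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  v <- result$consensus[upper.tri(result$consensus)]
  fn <- ecdf(v)
  x <- sort(unique(c(0, v, 1)))
  tibble(value = x, cdf = fn(x))
}

# Area under a consensus CDF (right-continuous step integral on [0, 1]).
consensus_cdf_area <- function(result) {
  cdf <- consensus_cdf(result)
  x <- cdf$value
  y <- cdf$cdf
  sum(diff(x) * y[-length(y)])
}

#' Relative change in consensus-CDF area across k
#'
#' The proportional increase in area under the consensus CDF when moving from
#' `k - 1` to `k` clusters (the raw area for the smallest k). A flat tail in
#' this curve marks the point beyond which added clusters no longer improve
#' stability.
#'
#' @param results A list of `consensus_result`s as returned by
#'   [consensus_cluster()].
#' @return A tibble `k`, `area`, `delta`.
#' @export
delta_area <- function(results) {
  ks <- vapply(results, function(r) r$k, numeric(1))
  ord <- order(ks)
  areas <- vapply(results[ord], consensus_cdf_area, numeric(1))
  ks <- ks[ord]
  delta <- c(areas[1], diff(areas) / head(areas, -1))
  tibble(k = ks, area = areas, delta = delta)
}

#' Gap statistic for the number of clusters
#'
#' Compares the log pooled within-cluster dispersion of the data against
#' reference datasets drawn uniformly over the (principal-component-aligned)
#' bounding box of the samples. `Gap(k) = mean_b log W*_kb - log W_k`, with
#' `W_k` the sum over clusters of within-cluster pairwise squared distances
#' divided by twice the cluster size. The reported `optimal_k` is the
#' smallest k with `Gap(k) >= Gap(k+1) - se(k+1)` (argmax fallback).
#'
#' @param expr genes x samples matrix.
#' @param k_range Cluster numbers to evaluate.
#' @param n_refs Number of reference datasets (>= 10).
#' @param seed Integer seed.
#' @param reference `"pca"` (rotated bounding box) or `"box"` (raw ranges).
#' @inheritParams hierarchical_cluster
#'
#' @return A `gap_curve`: tibble `k`, `log_w`, `e_log_w`, `gap`, `se` with
#'   attribute `optimal_k`.
#' @export
gap_statistic <- function(expr, k_range = 1:8, n_refs = 50, seed = 1L,
                          reference = c("pca", "box"),
                          linkage = "average",
                          distance = c("euclidean", "pearson")) {
  check_expr(expr)
  if (n_refs < 10) abort("n_refs must be at least 10")
  reference <- match.arg(reference)
  distance <- match.arg(distance)
  k_range <- sort(unique(as.integer(k_range)))
  n <- ncol(expr)
  if (any(k_range > n)) abort("k_range exceeds the number of samples")

  log_wk <- function(mat) {
    d <- as.matrix(sample_distance(mat, distance))^2
    if (all(d < 1e-24)) return(NULL) # degenerate: all samples identical
    tree <- hclust(as.dist(sqrt(d)), method = linkage)
    vapply(k_range, function(k) {
      cl <- if (k == 1) rep(1L, ncol(mat)) else cutree(tree, k = k)
      w <- sum(vapply(split(seq_len(ncol(mat)), cl), function(ix) {
        sum(d[ix, ix]) / (2 * length(ix))
      }, numeric(1)))
      log(max(w, .Machine$double.xmin))
    }, numeric(1))
  }

  obs <- log_wk(expr)
  if (is.null(obs)) {
    out <- tibble(k = k_range, log_w = NA_real_, e_log_w = NA_real_,
                  gap = NA_real_, se = NA_real_)
    attr(out, "optimal_k") <- 1L
    class(out) <- c("gap_curve", class(out))
    return(out)
  }

  x <- t(expr) # samples x genes
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (reference == "pca") {
    sv <- svd(xc, nu = 0)
    rot <- xc %*% sv$v
  } else {
    sv <- NULL
    rot <- xc
  }
  lo <- apply(rot, 2L, min)
  hi <- apply(rot, 2L, max)

  ref_logw <- with_seed(seed, {
    vapply(seq_len(n_refs), function(b) {
      z <- matrix(runif(n * ncol(rot)), n) %*% diag(hi - lo, ncol(rot)) +
        rep(lo, each = n)
      if (reference == "pca") z <- z %*% t(sv$v)
      log_wk(t(z))
    }, numeric(length(k_range)))
  })
  ref_logw <- matrix(ref_logw, nrow = length(k_range))

  e_log_w <- rowMeans(ref_logw)
  gap <- e_log_w - obs
  se <- apply(ref_logw, 1L, sd) * sqrt(1 + 1 / n_refs)

  optimal <- NA_integer_
  for (i in seq_len(length(k_range) - 1L)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) {
      optimal <- k_range[i]
      break
    }
  }
  if (is.na(optimal)) optimal <- k_range[which.max(gap)]

  out <- tibble(k = k_range, log_w = obs, e_log_w = e_log_w, gap = gap, se = se)
  attr(out, "optimal_k") <- as.integer(optimal)
  class(out) <- c("gap_curve", class(out))
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k = %d, %d samples, %d iterations (%.0f%% subsampling)\n",
              x$k, nrow(x$consensus), x$iterations, 100 * x$subsample_fraction))
  invisible(x)
}
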