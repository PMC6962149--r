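#' Significance analysis of microarrays (two-class, unpaired)
#'
#' Moderated difference statistic `d_i = (mean_B - mean_A) / (s_i + s0)` with
#' `s_i` the equal-variance pooled standard error and the exchangeability
#' constant `s0` chosen among percentiles of `s_i` to minimise the coefficient
#' of variation of the median absolute deviation of `d` across `s`-quantile
#' bins. False discovery rates come from a label-permutation null: for each
#' gene the median permutation count of statistics at least as extreme,
#' divided by the observed count, monotonised and capped at 1.
#'
#' @param expr genes x samples matrix (log scale).
#' @param binary_labels Logical or two-level vector over samples; `TRUE` (or
#'   the second level) is the group of interest (B).
#' @param n_permutations Permutations for the null; when this exceeds the
#'   number of distinct group assignments, all assignments are enumerated.
#' @param seed Integer seed for permutation sampling.
#'
#' @return A `sam_result` tibble `gene_id`, `d_score`, `q_value`, with
#'   attributes `s0` and `n_permutations`.
#' @export
sam_test <- function(expr, binary_labels, n_permutations = 1000, seed = 1L) {
  check_expr(expr)
  grp <- as_binary_groups(binary_labels, ncol(expr))
  n2 <- sum(grp)
  n1 <- sum(!grp)
  if (n1 < 2 || n2 < 2) abort("both groups need at least 2 samples")
  n <- n1 + n2

  x <- expr
  tot <- rowSums(x)
  tot2 <- rowSums(x^2)
  const <- (1 / n1 + 1 / n2) / (n - 2)

  d_of <- function(sum_b, sumsq_b, s0) {
    mean_b <- sum_b / n2
    mean_a <- (tot - sum_b) / n1
    ss_b <- sumsq_b - sum_b^2 / n2
    ss_a <- (tot2 - sumsq_b) - (tot - sum_b)^2 / n1
    s <- sqrt(pmax(const * (ss_a + ss_b), 0))
    list(d = (mean_b - mean_a) / (s + s0), s = s)
  }

  obs_sum <- rowSums(x[, grp, drop = FALSE])
  obs_sumsq <- rowSums(x[, grp, drop = FALSE]^2)
  base <- d_of(obs_sum, obs_sumsq, 0)
  s0 <- choose_s0(base$d * (base$s), base$s) # r_i = d * s when s0 = 0
  d_obs <- d_of(obs_sum, obs_sumsq, s0)$d

  # Distinct assignments of n2 samples to group B. Subsets are drawn at the
  # smaller group size and complemented when needed, so |d*| (and hence q) is
  # exactly invariant under a label flip.
  m_small <- min(n1, n2)
  n_distinct <- choose(n, m_small)
  if (n_permutations >= n_distinct && n_distinct <= 1e5) {
    small_idx <- combn(n, m_small, simplify = FALSE)
  } else {
    small_idx <- with_seed(seed, {
      lapply(seq_len(n_permutations), function(b) sort(sample.int(n, m_small)))
    })
  }
  perm_idx <- if (n2 == m_small) {
    small_idx
  } else {
    lapply(small_idx, function(ix) setdiff(seq_len(n), ix))
  }
  b_total <- length(perm_idx)

  abs_obs <- abs(d_obs)
  ord <- order(abs_obs) # ascending
  sorted_abs <- abs_obs[ord]
  counts <- matrix(0L, nrow = nrow(x), ncol = b_total)
  x2 <- x^2
  for (b in seq_len(b_total)) {
    idx <- perm_idx[[b]]
    db <- d_of(rowSums(x[, idx, drop = FALSE]), rowSums(x2[, idx, drop = FALSE]), s0)$d
    v <- sort(abs(db))
    # #{|d*| >= t} for each observed threshold t
    cnt_sorted <- length(v) - findInterval(sorted_abs, v, left.open = TRUE)
    counts[ord, b] <- cnt_sorted
  }
  med_null <- apply(counts, 1L, median)
  obs_count <- nrow(x) + 1 - rank(abs_obs, ties.method = "min")
  q <- pmin(med_null / obs_count, 1)
  # monotone: walking down from the largest |d|, q never decreases
  desc <- order(-abs_obs)
  q[desc] <- cummax(q[desc])

  out <- tibble(gene_id = rownames(x), d_score = unname(d_obs),
                q_value = unname(q))
  attr(out, "s0") <- s0
  attr(out, "n_permutations") <- b_total
  class(out) <- c("sam_result", class(out))
  out
}

# Coerce labels to logical group-of-interest indicator.
as_binary_groups <- function(labels, n) {
  if (length(labels) != n) abort("labels must have one entry per sample")
  if (is.logical(labels)) return(labels)
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) abort("labels must have exactly two levels")
  as.character(labels) == lev[2]
}

# SAM fudge factor: percentile of s minimising the coefficient of variation of
# the within-bin MAD of d across 100 s-quantile bins.
choose_s0 <- function(r, s) {
  cand <- unique(quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  n_bins <- min(100L, max(2L, length(s) %/% 10L))
  bins <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- vapply(split(d, bins), stats::mad, numeric(1))
    v <- v[is.finite(v)]
    if (mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}
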