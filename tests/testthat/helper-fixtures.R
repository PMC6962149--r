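# Shared fixtures, built in code. Heavier fixtures are memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(value), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small, well-separated 4-subtype cohort used across discovery/classifier
# tests: 48 samples x 400 genes, effect 3, noise 1.
small_cohort <- function() {
  memo("small_cohort", simulate_cohort(cohort_spec(
    n_samples = 48, n_genes = 400, k_subtypes = 4, genes_per_signature = 10,
    signature_effect = 3, noise_sd = 1, batch_count = 1, censor_rate = 0,
    seed = 42
  )))
}

# Two well-separated Gaussian blobs in gene space (genes x samples).
two_blob_matrix <- function(n_per = 10, n_genes = 60, shift = 4, seed = 11) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per), nrow = n_genes)
  m[1:20, seq_len(n_per)] <- m[1:20, seq_len(n_per)] + shift
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(2 * n_per)))
  attr(m, "blob") <- rep(c("A", "B"), each = n_per)
  m
}

# k planted blobs, each with its own up-shifted gene block.
blob_matrix <- function(k = 4, n_per = 10, genes_per = 15, extra_genes = 40,
                        shift = 4, seed = 5) {
  set.seed(seed)
  n_genes <- k * genes_per + extra_genes
  n <- k * n_per
  m <- matrix(rnorm(n_genes * n), nrow = n_genes)
  lab <- rep(seq_len(k), each = n_per)
  for (i in seq_len(k)) {
    rows <- ((i - 1) * genes_per + 1):(i * genes_per)
    m[rows, lab == i] <- m[rows, lab == i] + shift
  }
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n)))
  attr(m, "blob") <- lab
  m
}

# Agreement of two labelings up to renaming (max one-to-one overlap fraction,
# greedy), enough for well-separated cases.
label_agreement <- function(a, b) {
  tab <- table(a, b)
  agree <- 0
  while (length(tab) && nrow(tab) && ncol(tab)) {
    ix <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    agree <- agree + tab[ix[1], ix[2]]
    tab <- tab[-ix[1], -ix[2], drop = FALSE]
  }
  agree / length(a)
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Log-rank statistic from first principles: at each distinct event time,
# observed vs expected events per group with the hypergeometric variance.
logrank_oracle <- function(time, event, group) {
  group <- as.character(group)
  g2 <- sort(unique(group))[2]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    d <- sum(event == 1 & time == t)
    n <- sum(at_risk)
    n2 <- sum(at_risk & group == g2)
    d2 <- sum(event == 1 & time == t & group == g2)
    o_minus_e <- o_minus_e + (d2 - d * n2 / n)
    if (n > 1) v <- v + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}
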