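# Subtype signature construction and the nearest-shrunken-centroid classifier.

#' Rank genes by ROC AUC for a binary contrast
#'
#' Per gene, the AUC is the fraction of (positive, negative) sample pairs in
#' which the positive sample has higher expression, ties counted one half
#' (the Mann-Whitney identity). Discriminativeness is two-sided:
#' `max(auc, 1 - auc)`, so low-expression markers rank as well as high ones.
#'
#' @param expr genes x samples matrix.
#' @param binary_labels Logical or two-level vector; `TRUE`/second level is
#'   the positive group.
#'
#' @return A tibble `gene_id`, `auc`, `discriminativeness`, sorted by
#'   decreasing discriminativeness.
#' @export
auc_rank <- function(expr, binary_labels) {
  check_expr(expr)
  pos <- as_binary_groups(binary_labels, ncol(expr))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) abort("both groups must be non-empty")
  auc <- apply(expr, 1L, function(x) {
    r <- rank(x)
    (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  })
  out <- tibble(
    gene_id = rownames(expr),
    auc = unname(auc),
    discriminativeness = pmax(auc, 1 - auc)
  )
  dplyr::arrange(out, dplyr::desc(.data$discriminativeness), .data$gene_id)
}

#' Build a subtype gene signature (SAM filter + AUC top-n)
#'
#' For every subtype, genes differential between that subtype and the rest at
#' SAM `q < fdr_max` are ranked by two-sided AUC discriminativeness and the
#' top `top_n` retained (ties broken by smaller q, then gene id); the
#' signature is the deduplicated union across subtypes, so its size is at
#' most `k * top_n` (fewer when classes share markers).
#'
#' @param expr genes x samples matrix.
#' @param labels Subtype labeling (tibble `sample_id`, `label` or named
#'   vector), covering the samples of `expr`.
#' @param fdr_max SAM q-value cut-off.
#' @param top_n Markers kept per subtype.
#' @param n_permutations,seed Passed to [sam_test()].
#'
#' @return Character vector of signature gene ids (sorted), with attribute
#'   `per_class`: the named list of per-subtype top gene lists.
#' @export
build_signature <- function(expr, labels, fdr_max = 0.01, top_n = 40,
                            n_permutations = 1000, seed = 1L) {
  check_expr(expr)
  lab <- as_labeling(labels)
  lab <- lab[match(colnames(expr), lab$sample_id), ]
  if (anyNA(lab$label)) abort("labels must cover all samples in `expr`")
  classes <- sort(unique(lab$label))
  if (length(classes) < 2) abort("need at least 2 classes")

  per_class <- lapply(classes, function(cl) {
    in_class <- lab$label == cl
    sam <- sam_test(expr, in_class, n_permutations = n_permutations, seed = seed)
    sig <- sam$gene_id[sam$q_value < fdr_max]
    if (length(sig) == 0) {
      warn(sprintf("no SAM-significant genes for class '%s'", cl))
      return(character(0))
    }
    ranking <- auc_rank(expr[sig, , drop = FALSE], in_class)
    ranking$q_value <- sam$q_value[match(ranking$gene_id, sam$gene_id)]
    ranking <- dplyr::arrange(ranking, dplyr::desc(.data$discriminativeness),
                              .data$q_value, .data$gene_id)
    head(ranking$gene_id, top_n)
  })
  names(per_class) <- classes
  out <- sort(unique(unlist(per_class)))
  attr(out, "per_class") <- per_class
  out
}

#' Train a nearest-shrunken-centroid (PAM) subtype classifier
#'
#' Class centroids of the signature genes are shrunk toward the overall
#' centroid by soft-thresholding the standardized offsets
#' `d_kj = (centroid_kj - overall_j) / (m_k (s_j + s0))`, where `s_j` is the
#' pooled within-class standard deviation, `s0` its median, and
#' `m_k = sqrt(1/n_k - 1/n)`. The shrinkage threshold is chosen by stratified
#' cross-validation as the value minimising misclassification (smallest
#' threshold among ties); class priors are the empirical frequencies.
#'
#' @param expr genes x samples training matrix.
#' @param labels Subtype labeling of the training samples.
#' @param signature Character vector of signature genes (subset of `expr`
#'   rows).
#' @param cv_folds Number of stratified folds.
#' @param seed Integer seed for fold assignment.
#' @param n_thresholds Size of the threshold grid between 0 and `max |d_kj|`.
#'
#' @return A `centroid_classifier` object.
#' @export
train_centroid_classifier <- function(expr, labels, signature, cv_folds = 5L,
                                      seed = 1L, n_thresholds = 30L) {
  check_expr(expr)
  missing <- setdiff(signature, rownames(expr))
  if (length(missing)) {
    abort(sprintf("signature gene(s) absent from expr: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  lab <- as_labeling(labels)
  lab <- lab[match(colnames(expr), lab$sample_id), ]
  if (anyNA(lab$label)) abort("labels must cover all samples in `expr`")
  y <- lab$label
  counts <- table(y)
  if (any(counts < cv_folds)) {
    abort("every class must have at least `cv_folds` members")
  }
  x <- expr[signature, , drop = FALSE]

  fit0 <- fit_centroids(x, y)
  thresholds <- seq(0, max(abs(fit0$d)), length.out = n_thresholds)

  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cl in names(counts)) {
      ix <- which(y == cl)
      f[ix] <- sample(rep_len(seq_len(cv_folds), length(ix)))
    }
    f
  })

  errs <- matrix(0, nrow = cv_folds, ncol = length(thresholds))
  for (fold in seq_len(cv_folds)) {
    test <- folds == fold
    fit <- fit_centroids(x[, !test, drop = FALSE], y[!test])
    for (ti in seq_along(thresholds)) {
      pred <- predict_centroids(fit, thresholds[ti], x[, test, drop = FALSE])
      errs[fold, ti] <- sum(pred$label != y[test])
    }
  }
  cv_err <- colSums(errs) / length(y)
  best <- thresholds[which.min(cv_err)] # which.min takes the smallest on ties

  structure(
    list(
      signature_genes = rownames(x),
      class_ids = fit0$classes,
      overall_centroid = fit0$overall,
      centroids = fit0$centroids,
      shrunken_offsets = soft_threshold(fit0$d, best),
      shrinkage_threshold = best,
      class_priors = fit0$priors,
      pooled_sd = fit0$s,
      s0_pam = fit0$s0,
      m_k = fit0$m_k,
      cv_error = tibble(threshold = thresholds, error = cv_err)
    ),
    class = "centroid_classifier"
  )
}

# Centroid statistics for a training split.
fit_centroids <- function(x, y) {
  classes <- sort(unique(y))
  n <- length(y)
  k <- length(classes)
  nk <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  overall <- rowMeans(x)
  centroids <- vapply(classes, function(cl) rowMeans(x[, y == cl, drop = FALSE]),
                      numeric(nrow(x)))
  centroids <- matrix(centroids, nrow = nrow(x),
                      dimnames = list(rownames(x), classes))
  ss <- 0
  for (cl in classes) {
    dev <- x[, y == cl, drop = FALSE] - centroids[, cl]
    ss <- ss + rowSums(dev^2)
  }
  s <- sqrt(ss / (n - k))
  s0 <- median(s)
  m_k <- sqrt(pmax(1 / nk - 1 / n, 0))
  d <- sweep(centroids - overall, 2L, m_k, "/") / (s + s0)
  list(classes = classes, overall = overall, centroids = centroids,
       s = s, s0 = s0, m_k = m_k, d = d, priors = nk / n,
       nk = nk)
}

soft_threshold <- function(d, delta) {
  sign(d) * pmax(abs(d) - delta, 0)
}

# Posterior classification from centroid statistics at threshold delta.
predict_centroids <- function(fit, delta, newx) {
  d_shr <- soft_threshold(fit$d, delta)
  shrunken <- fit$overall + sweep(d_shr, 2L, fit$m_k, "*") * (fit$s + fit$s0)
  denom <- (fit$s + fit$s0)^2
  disc <- vapply(seq_along(fit$classes), function(ki) {
    colSums((newx - shrunken[, ki])^2 / denom) - 2 * log(fit$priors[ki])
  }, numeric(ncol(newx)))
  disc <- matrix(disc, nrow = ncol(newx),
                 dimnames = list(colnames(newx), fit$classes))
  z <- -disc / 2
  z <- z - apply(z, 1L, max)
  post <- exp(z) / rowSums(exp(z))
  list(
    label = fit$classes[max.col(post, ties.method = "first")],
    posterior = post
  )
}

#' Classify samples with a trained centroid classifier
#'
#' Gaussian discriminant scores against the shrunken class centroids,
#' `delta_k(x) = sum_j (x_j - centroid'_kj)^2 / (s_j + s0)^2 - 2 log prior_k`,
#' turned into posterior probabilities via `posterior_k %prop%
#' exp(-delta_k / 2)`; each sample is assigned the posterior-maximal subtype.
#'
#' @param model A `centroid_classifier`.
#' @param expr genes x samples matrix containing all signature genes (run
#'   [cross_platform_prepare()] first for external cohorts).
#'
#' @return A tibble `sample_id`, `label`, plus one posterior column per class.
#' @export
classify <- function(model, expr) {
  stopifnot(inherits(model, "centroid_classifier"))
  check_expr(expr)
  missing <- setdiff(model$signature_genes, rownames(expr))
  if (length(missing)) {
    abort(sprintf("expr is missing signature gene(s): %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  x <- expr[model$signature_genes, , drop = FALSE]
  fit <- list(
    classes = model$class_ids, overall = model$overall_centroid,
    s = model$pooled_sd, s0 = model$s0_pam, m_k = model$m_k,
    d = model$shrunken_offsets, priors = model$class_priors
  )
  pred <- predict_centroids(fit, 0, x) # offsets already thresholded
  out <- tibble(sample_id = colnames(x), label = pred$label)
  dplyr::bind_cols(out, as_tibble(pred$posterior))
}

#' Harmonise two cohorts for cross-platform classification
#'
#' Restricts both expression matrices to their shared genes (identically
#' ordered) and, by default, median-centers every gene within each cohort so
#' platform-level location shifts cancel.
#'
#' @param expr_a,expr_b genes x samples matrices.
#' @param center Median-center each cohort per gene.
#'
#' @return A list with elements `a` and `b`.
#' @export
cross_platform_prepare <- function(expr_a, expr_b, center = TRUE) {
  check_expr(expr_a, "expr_a")
  check_expr(expr_b, "expr_b")
  shared <- intersect(rownames(expr_a), rownames(expr_b))
  if (length(shared) == 0) abort("no shared genes between the cohorts")
  shared <- sort(shared)
  a <- expr_a[shared, , drop = FALSE]
  b <- expr_b[shared, , drop = FALSE]
  if (center) {
    a <- median_center(a)
    b <- median_center(b)
  }
  list(a = a, b = b)
}

#' Per-class gene-set z-scores
#'
#' Expression is row-standardized, each sample scored by the mean over the
#' (deduplicated) set genes, and each class summarised by the mean of its
#' sample scores multiplied by the square root of the effective set size.
#'
#' @param expr genes x samples matrix.
#' @param gene_set Character vector of gene ids.
#' @param labels Subtype labeling over the samples.
#'
#' @return A tibble `label`, `zscore`.
#' @export
gene_set_zscore <- function(expr, gene_set, labels) {
  check_expr(expr)
  genes <- intersect(unique(gene_set), rownames(expr))
  if (length(genes) == 0) abort("gene_set does not intersect the expression genes")
  lab <- as_labeling(labels)
  lab <- lab[match(colnames(expr), lab$sample_id), ]
  if (anyNA(lab$label)) abort("labels must cover all samples in `expr`")
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1L, sd)
  sdv[sdv == 0] <- Inf # constant genes contribute 0
  z <- (expr - mu) / sdv
  sample_score <- colMeans(z[genes, , drop = FALSE])
  scores <- tapply(sample_score, lab$label, mean) * sqrt(length(genes))
  tibble(label = names(scores), zscore = as.numeric(scores))
}
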