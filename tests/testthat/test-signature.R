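test_that("AUC matches pair enumeration and the Mann-Whitney identity", {
  m <- rbind(
    perfect = c(3, 4, 1, 2),
    ties = c(5, 5, 5, 5),
    mixed = c(2, 4, 1, 3)
  )
  colnames(m) <- paste0("s", 1:4)
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  res <- auc_rank(m, pos)
  expect_equal(res$auc[res$gene_id == "perfect"], 1)
  expect_equal(res$auc[res$gene_id == "ties"], 0.5)
  # pairs: 2>1, 2<3, 4>1, 4>3 -> 3/4
  expect_equal(res$auc[res$gene_id == "mixed"], 0.75)

  # label flip maps auc -> 1 - auc
  flipped <- auc_rank(m, !pos)
  expect_equal(flipped$auc[match(res$gene_id, flipped$gene_id)], 1 - res$auc)
})

test_that("AUC agrees with the pROC oracle on random data", {
  skip_if_not_installed("pROC")
  set.seed(6)
  m <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:30)))
  pos <- rep(c(FALSE, TRUE), 15)
  res <- auc_rank(m, pos)
  for (g in rownames(m)) {
    oracle <- as.numeric(pROC::auc(pROC::roc(pos, m[g, ], quiet = TRUE,
                                             direction = "<")))
    expect_equal(res$auc[res$gene_id == g], oracle, tolerance = 1e-10)
  }
})

test_that("build_signature selects planted markers and dedupes the union", {
  cohort <- small_cohort()
  sig <- build_signature(cohort$expression, cohort$truth_labels,
                         n_permutations = 100, seed = 1, top_n = 10)
  expect_lte(length(sig), 4 * 10)
  per_class <- attr(sig, "per_class")
  for (s in paste0("PDACS", 1:4)) {
    planted <- cohort$signature_genes[[s]]
    expect_gte(mean(planted %in% per_class[[s]]), 0.9)
  }

  # shuffled labels: empty or near-empty signature
  set.seed(8)
  shuffled <- dplyr::mutate(cohort$truth_labels, label = sample(.data$label))
  sig_null <- suppressWarnings(build_signature(
    cohort$expression, shuffled, n_permutations = 100, seed = 1, top_n = 10
  ))
  expect_lte(length(sig_null), 5)

  # two classes sharing the single informative gene: union of size 1
  set.seed(9)
  m <- matrix(rnorm(50 * 20, sd = 0.5), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  m[1, 1:10] <- m[1, 1:10] + 5 # up in class A, down in class B: informative both ways
  lab <- tibble::tibble(sample_id = colnames(m),
                        label = rep(c("A", "B"), each = 10))
  sig_shared <- suppressWarnings(build_signature(m, lab, n_permutations = 200,
                                                 seed = 2, top_n = 40))
  expect_true("g01" %in% sig_shared)
  expect_lte(length(sig_shared), 3)
})

test_that("centroid classifier reduces to nearest centroid at zero shrinkage", {
  cohort <- small_cohort()
  genes <- unlist(cohort$signature_genes)
  x <- cohort$expression[genes, ]
  lab <- cohort$truth_labels
  model <- train_centroid_classifier(cohort$expression, lab, genes,
                                     cv_folds = 3, seed = 1, n_thresholds = 5)

  fit <- pdacsubtype:::fit_centroids(x, lab$label)
  pred0 <- pdacsubtype:::predict_centroids(fit, 0, x)
  # plain nearest-centroid discriminant (delta = 0): same standardized metric
  manual <- apply(x, 2, function(col) {
    d <- colSums((col - fit$centroids)^2 / (fit$s + fit$s0)^2) -
      2 * log(fit$priors)
    names(which.min(d))
  })
  expect_equal(unname(pred0$label), unname(manual))

  # total shrinkage: every sample goes to the prior-maximal class
  huge <- max(abs(fit$d)) + 1
  pred_all <- pdacsubtype:::predict_centroids(fit, huge, x)
  expect_true(all(pred_all$label == names(which.max(fit$priors))))
})

test_that("classifier posteriors are valid and recover planted subtypes", {
  big <- simulate_cohort(cohort_spec(
    n_samples = 96, n_genes = 400, k_subtypes = 4, genes_per_signature = 10,
    signature_effect = 3, noise_sd = 1, batch_count = 1, censor_rate = 0,
    seed = 44
  ))
  sig <- unlist(big$signature_genes)
  train_ids <- big$truth_labels$sample_id[1:48]
  test_ids <- big$truth_labels$sample_id[49:96]
  train_lab <- dplyr::filter(big$truth_labels, .data$sample_id %in% train_ids)
  holdout_lab <- dplyr::filter(big$truth_labels, .data$sample_id %in% test_ids)

  model <- train_centroid_classifier(big$expression[, train_ids], train_lab,
                                     sig, cv_folds = 3, seed = 1)
  pred <- classify(model, big$expression[, test_ids])
  post <- as.matrix(pred[, model$class_ids])
  expect_true(all(post >= 0))
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-8)
  acc <- mean(pred$label == holdout_lab$label[match(pred$sample_id,
                                                    holdout_lab$sample_id)])
  expect_gte(acc, 0.9)

  # sample equal to a class centroid gets that class (equal priors irrelevant here)
  centro <- model$overall_centroid +
    (model$shrunken_offsets[, "PDACS2"] * model$m_k["PDACS2"]) *
      (model$pooled_sd + model$s0_pam)
  probe <- matrix(centro, ncol = 1,
                  dimnames = list(model$signature_genes, "probe"))
  expect_equal(classify(model, probe)$label, "PDACS2")

  expect_error(classify(model, big$expression[setdiff(rownames(big$expression),
                                                      sig[1]), ]), "missing")
  expect_error(
    train_centroid_classifier(big$expression, big$truth_labels,
                              c(sig, "NOPE"), cv_folds = 3),
    "NOPE"
  )
})

test_that("two-class symmetric sample gets posteriors (0.5, 0.5)", {
  # symmetric toy: centroids mirrored, equal priors
  set.seed(10)
  m <- matrix(rnorm(20 * 12, sd = 0.4), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12)))
  m[1:10, 1:6] <- m[1:10, 1:6] + 2
  m[11:20, 7:12] <- m[11:20, 7:12] + 2
  lab <- tibble::tibble(sample_id = colnames(m),
                        label = rep(c("A", "B"), each = 6))
  model <- train_centroid_classifier(m, lab, rownames(m), cv_folds = 2,
                                     seed = 1, n_thresholds = 3)
  shrA <- model$overall_centroid + model$shrunken_offsets[, "A"] *
    model$m_k["A"] * (model$pooled_sd + model$s0_pam)
  shrB <- model$overall_centroid + model$shrunken_offsets[, "B"] *
    model$m_k["B"] * (model$pooled_sd + model$s0_pam)
  midpoint <- matrix((shrA + shrB) / 2, ncol = 1,
                     dimnames = list(model$signature_genes, "mid"))
  pred <- classify(model, midpoint)
  expect_equal(pred$A, 0.5, tolerance = 1e-8)
  expect_equal(pred$B, 0.5, tolerance = 1e-8)
})

test_that("cross-platform preparation removes global shifts", {
  cohort <- small_cohort()
  a <- cohort$expression
  b <- a + 5
  colnames(b) <- paste0("ext_", colnames(b))
  prep <- cross_platform_prepare(a, b)
  expect_identical(rownames(prep$a), rownames(prep$b))
  expect_equal(unname(prep$a), unname(prep$b), tolerance = 1e-12)

  sig <- unlist(cohort$signature_genes)
  model <- train_centroid_classifier(prep$a, cohort$truth_labels, sig,
                                     cv_folds = 3, seed = 1)
  lab_orig <- classify(model, prep$a)$label
  lab_shift <- classify(model, prep$b)$label
  expect_equal(lab_shift, lab_orig)

  # intersection semantics
  x <- a[1:3, ]
  y <- a[2:4, ]
  rownames(y) <- rownames(a)[2:4]
  prep2 <- cross_platform_prepare(x, y, center = FALSE)
  expect_setequal(rownames(prep2$a), rownames(a)[2:3])
  expect_error(cross_platform_prepare(a[1:2, ], a[3:4, ]), "shared")
})

test_that("gene-set z-scores single out the matching subtype", {
  cohort <- small_cohort()
  z_all <- gene_set_zscore(cohort$expression, rownames(cohort$expression),
                           cohort$truth_labels)
  expect_true(all(abs(z_all$zscore) < 2.5))

  z_sig <- gene_set_zscore(cohort$expression, cohort$signature_genes$PDACS3,
                           cohort$truth_labels)
  expect_equal(z_sig$label[which.max(z_sig$zscore)], "PDACS3")

  # duplicated genes in the set count once
  dup <- gene_set_zscore(cohort$expression,
                         rep(cohort$signature_genes$PDACS3, 2),
                         cohort$truth_labels)
  expect_equal(dup$zscore, z_sig$zscore)

  expect_error(gene_set_zscore(cohort$expression, c("NOPE"), cohort$truth_labels),
               "intersect")
})
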