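test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_samples = 3, k_subtypes = 4,
                           subtype_median_os = c(1, 1, 1, 1)), "n_samples")
  expect_error(cohort_spec(n_genes = 100, genes_per_signature = 40,
                           k_subtypes = 4), "genes_per_signature")
  expect_error(cohort_spec(subtype_median_os = c(10, 20)), "subtype_median_os")
  expect_error(cohort_spec(censor_rate = 1.5), "censor_rate")
})

test_that("planted signatures shift group means by the specified effect", {
  cohort <- simulate_cohort(cohort_spec(
    n_samples = 90, n_genes = 500, k_subtypes = 4, genes_per_signature = 40,
    signature_effect = 3, noise_sd = 1, batch_count = 1, seed = 7
  ))
  expect_setequal(unique(cohort$truth_labels$label), paste0("PDACS", 1:4))
  for (s in paste0("PDACS", 1:4)) {
    in_s <- cohort$truth_labels$sample_id[cohort$truth_labels$label == s]
    out_s <- setdiff(colnames(cohort$expression), in_s)
    genes <- cohort$signature_genes[[s]]
    gap <- mean(cohort$expression[genes, in_s]) - mean(cohort$expression[genes, out_s])
    expect_equal(gap, 3, tolerance = 0.15)
  }
  # signature gene lists are disjoint across subtypes
  expect_equal(anyDuplicated(unlist(cohort$signature_genes)), 0L)
  expect_true(all(is.finite(cohort$expression)))
})

test_that("zero effect leaves no separation beyond noise", {
  cohort <- simulate_cohort(cohort_spec(
    n_samples = 60, n_genes = 300, k_subtypes = 4, genes_per_signature = 20,
    signature_effect = 0, noise_sd = 1, batch_count = 1, seed = 3
  ))
  for (s in paste0("PDACS", 1:2)) {
    in_s <- cohort$truth_labels$sample_id[cohort$truth_labels$label == s]
    out_s <- setdiff(colnames(cohort$expression), in_s)
    genes <- cohort$signature_genes[[s]]
    gap <- mean(cohort$expression[genes, in_s]) - mean(cohort$expression[genes, out_s])
    expect_lt(abs(gap), 0.5)
  }
})

test_that("identical spec and seed give bit-identical cohorts", {
  a <- simulate_cohort(cohort_spec(n_samples = 30, n_genes = 100, seed = 9,
                                   genes_per_signature = 10))
  b <- simulate_cohort(cohort_spec(n_samples = 30, n_genes = 100, seed = 9,
                                   genes_per_signature = 10))
  d <- simulate_cohort(cohort_spec(n_samples = 30, n_genes = 100, seed = 10,
                                   genes_per_signature = 10))
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_false(identical(a$expression, d$expression))
})

test_that("survival generation matches the specified exponential medians", {
  medians <- c(14.7, 31.8, 21.5, 14.0)
  cohort <- simulate_cohort(cohort_spec(
    n_samples = 2000, n_genes = 8, k_subtypes = 4, genes_per_signature = 0,
    subtype_median_os = medians, censor_rate = 0, batch_count = 1, seed = 21
  ))
  km <- km_estimate(dplyr::mutate(cohort$clinical, group = .data$subtype_truth))
  est <- glance(km)
  est <- est[order(est$group), ]
  expect_equal(est$median, medians, tolerance = 0.1)
})

test_that("batch shifts are additive location offsets", {
  base <- cohort_spec(n_samples = 40, n_genes = 200, genes_per_signature = 0,
                      batch_count = 2, batch_shift = 2, seed = 5)
  cohort <- simulate_cohort(base)
  b <- cohort$batches[colnames(cohort$expression)]
  diff <- mean(cohort$expression[, b == "batch2"]) -
    mean(cohort$expression[, b == "batch1"])
  expect_equal(diff, 2, tolerance = 0.1)
})

test_that("pdx simulation plants compartment-exclusive genes and exact splits", {
  sim <- simulate_pdx_pairs(pdx_sim_spec(
    n_pdx = 6, n_genes = 400, n_epithelial_exclusive = 50,
    n_stromal_exclusive = 40, seed = 13
  ))
  map <- setNames(sim$homology$mouse_gene, sim$homology$human_gene)
  for (p in sim$pairs) {
    # epithelial-exclusive genes never carry mouse-mapped counts
    mapped_epi <- intersect(sim$truth$epithelial, names(map))
    expect_true(all(p$mouse_counts[map[mapped_epi]] == 0))
    expect_true(all(p$human_counts[sim$truth$stromal] == 0))
  }

  # fixed human fraction: shared genes split exactly before rounding
  sim2 <- simulate_pdx_pairs(pdx_sim_spec(
    n_pdx = 3, n_genes = 200, n_epithelial_exclusive = 0,
    n_stromal_exclusive = 0, human_fraction_range = c(0.75, 0.75),
    count_noise_sdlog = 0, seed = 2
  ))
  fr <- species_fraction(sim2$pairs)
  mapped <- sim2$homology$human_gene
  for (p in sim2$pairs) {
    h <- p$human_counts[mapped]
    m <- p$mouse_counts[setNames(sim2$homology$mouse_gene, mapped)[mapped]]
    total <- h + m
    expect_true(all(abs(h - 0.75 * total) <= 1))
  }
  expect_true(all(abs(fr$human_fraction - 0.75) < 0.01))

  # determinism
  rerun <- simulate_pdx_pairs(pdx_sim_spec(
    n_pdx = 6, n_genes = 400, n_epithelial_exclusive = 50,
    n_stromal_exclusive = 40, seed = 13
  ))
  expect_identical(sim$pairs[[1]]$human_counts, rerun$pairs[[1]]$human_counts)
  expect_identical(sim$pairs[[4]]$mouse_counts, rerun$pairs[[4]]$mouse_counts)
})

test_that("species fractions round-trip the drawn simulator fractions", {
  sim <- simulate_pdx_pairs(pdx_sim_spec(n_pdx = 8, n_genes = 2000,
                                         n_epithelial_exclusive = 60,
                                         n_stromal_exclusive = 60, seed = 4))
  fr <- species_fraction(sim$pairs)
  expect_equal(fr$human_fraction, unname(sim$human_fractions), tolerance = 0.02)
  expect_equal(fr$human_fraction + fr$mouse_fraction, rep(1, 8))
})

test_that("alternative labelings degrade with the agreement parameter", {
  truth <- small_cohort()$truth_labels

  # agreement 1: a renamed copy; corresponding subtypes have Jaccard 1
  alt1 <- simulate_alternative_labeling(truth, agreement = 1, seed = 8)
  tab <- table(truth$label, alt1$label)
  expect_true(all(rowSums(tab > 0) == 1)) # one-to-one renaming
  for (lv in rownames(tab)) {
    partner <- colnames(tab)[which.max(tab[lv, ])]
    expect_equal(jaccard(truth$sample_id[truth$label == lv],
                         alt1$sample_id[alt1$label == partner]), 1)
  }

  # agreement 0.9, larger n: corresponding-subtype Jaccard is high
  big_truth <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:400),
    label = rep(paste0("PDACS", 1:4), each = 100)
  )
  alt <- simulate_alternative_labeling(big_truth, agreement = 0.9, seed = 30)
  tab <- table(big_truth$label, alt$label)
  for (lv in rownames(tab)) {
    partner <- colnames(tab)[which.max(tab[lv, ])]
    expect_gt(jaccard(big_truth$sample_id[big_truth$label == lv],
                      alt$sample_id[alt$label == partner]), 0.6)
  }

  expect_error(simulate_alternative_labeling(truth, agreement = 2), "agreement")
})
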