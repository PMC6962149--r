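make_pair <- function(id, human, mouse) {
  structure(list(sample_id = id, human_counts = human, mouse_counts = mouse),
            class = "pdx_sample_pair")
}

test_that("species_fraction computes simple read proportions", {
  p <- make_pair("P1", c(g1 = 750000), c(mg1 = 250000))
  fr <- species_fraction(p)
  expect_equal(fr$human_fraction, 0.75)
  expect_equal(fr$mouse_fraction, 0.25)

  p2 <- make_pair("P2", c(g1 = 10), c(mg1 = 0))
  expect_equal(species_fraction(p2)$human_fraction, 1)

  p0 <- make_pair("P0", c(g1 = 0), c(mg1 = 0))
  expect_error(species_fraction(p0), "P0")
})

test_that("combine_expression sums homologs and normalizes to log2 RPM", {
  homology <- tibble::tibble(human_gene = c("A", "B"), mouse_gene = c("mA", "mB"))
  # gene A: human 100 + mouse 50 = 150 of a combined library of 1e6
  pair <- make_pair("P1",
                    c(A = 100, B = 1e6 - 150),
                    c(mA = 50, mB = 0))
  out <- combine_expression(list(pair), homology)
  expect_equal(out["A", "P1"], log2(151))

  # unmapped human gene keeps only its human counts
  hom2 <- tibble::tibble(human_gene = "A", mouse_gene = "mA")
  pair2 <- make_pair("P2", c(A = 100, B = 300), c(mA = 100, mB = 999))
  out2 <- combine_expression(list(pair2), hom2)
  rpm_b <- 300 / 500 * 1e6
  expect_equal(out2["B", "P2"], log2(rpm_b + 1))

  # per-sample pre-log RPM sums to 1e6
  sim <- simulate_pdx_pairs(pdx_sim_spec(n_pdx = 4, n_genes = 300,
                                         n_epithelial_exclusive = 20,
                                         n_stromal_exclusive = 20, seed = 6))
  comb <- combine_expression(sim$pairs, sim$homology)
  rpm <- 2^comb - 1
  expect_equal(unname(colSums(rpm)), rep(1e6, 4), tolerance = 1e-9)

  # all-zero sample is an error naming the sample
  bad <- make_pair("PX", c(A = 0, B = 0), c(mA = 0, mB = 0))
  expect_error(combine_expression(list(bad), homology), "PX")
})

test_that("correlation of correlations separates concordant structure", {
  set.seed(14)
  n_genes <- 40
  n_samp <- 30
  # concordant block: same latent factor drives genes 1-15 in both datasets
  make_data <- function(flip_block) {
    f <- rnorm(n_samp)
    g <- rnorm(n_samp)
    m <- matrix(rnorm(n_genes * n_samp, sd = 0.6), n_genes, n_samp)
    m[1:15, ] <- m[1:15, ] + 2.2 * rep(f, each = 15)
    driver <- if (flip_block) g else f
    m[16:30, ] <- m[16:30, ] + 2.2 * rep(driver, each = 15)
    dimnames(m) <- list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:n_samp))
    m
  }
  donor <- make_data(FALSE)
  pdx <- make_data(TRUE) # second block driven by an unrelated factor
  res <- correlation_of_correlations(donor, pdx, coeff_min = 0.25, sd_min = 0)
  expect_gte(mean(res$pass_coefficient[1:15]), 0.9) # concordant block kept

  # identical datasets: every coefficient is 1
  res_id <- correlation_of_correlations(donor, donor)
  expect_true(all(res_id$coefficient > 0.999))

  # independent noise: few stage-1 survivors
  survivors <- vapply(1:5, function(s) {
    set.seed(200 + s)
    a <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
    b <- matrix(rnorm(50 * 20), 50, 20, dimnames = dimnames(a))
    mean(correlation_of_correlations(a, b)$pass_coefficient)
  }, numeric(1))
  expect_lte(mean(survivors), 0.1)

  expect_error(correlation_of_correlations(donor[, 1:2], pdx), "3 samples")
})

test_that("compartment gene rules apply literally, including the as-written clause", {
  mk <- function(min_ep, max_ep, min_str, max_str) {
    h <- rbind(c(min_ep, max_ep))
    m <- rbind(c(min_str, max_str))
    dimnames(h) <- list("g", c("s1", "s2"))
    dimnames(m) <- list("g", c("s1", "s2"))
    select_compartment_genes(h, m)
  }
  # min.ep 2.0, max.str 0.5 -> epithelial by clause 1
  expect_equal(mk(2, 2, 0.5, 0.5)$epithelial, "g")
  # min.ep 6.2, max.str 1.0 -> epithelial via second clause (5.2 > 5)
  res <- mk(6.2, 6.2, 1, 1)
  expect_equal(res$epithelial, "g")
  # min.str 2.0, max.ep 1.0 -> NOT stromal (difference 1.0 <= 1.25)
  expect_equal(mk(1, 1, 2, 2)$stromal, character(0))
  # min.str 3.0, max.ep 1.0 -> stromal by clause 1
  expect_equal(mk(1, 1, 3, 3)$stromal, "g")

  # as-written second stromal clause keys on min.ep - max.str: an extreme
  # epithelial gene matches both rules and is dropped with a warning
  h <- rbind(g = c(10, 10.5))
  m <- rbind(g = c(0, 0))
  colnames(h) <- colnames(m) <- c("s1", "s2")
  expect_warning(res_conflict <- select_compartment_genes(h, m), "both")
  expect_equal(res_conflict$epithelial, character(0))
  # the symmetric variant keeps it epithelial
  res_sym <- select_compartment_genes(h, m, stromal_rule = "symmetric")
  expect_equal(res_sym$epithelial, "g")
  expect_equal(res_sym$stromal, character(0))
})

test_that("planted compartment-exclusive genes are recovered exactly", {
  sim <- simulate_pdx_pairs(pdx_sim_spec(
    n_pdx = 10, n_genes = 800, n_epithelial_exclusive = 60,
    n_stromal_exclusive = 50, count_noise_sdlog = 0, seed = 17
  ))
  comp <- compartment_expression(sim$pairs, sim$homology)
  sets <- select_compartment_genes(comp$human, comp$mouse)
  expect_setequal(sets$epithelial, sim$truth$epithelial)
  expect_setequal(sets$stromal, sim$truth$stromal)
})

test_that("compartment normalization removes per-sample dilution shifts", {
  set.seed(18)
  m <- matrix(rnorm(30 * 6, mean = 5), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:6)))
  anchor <- sprintf("g%02d", 1:10)
  # sample 2 carries the same tumor profile as sample 1, diluted by +1 log2
  diluted <- m
  diluted[, 2] <- diluted[, 1] + 1
  norm <- compartment_normalize(diluted, anchor)
  expect_equal(norm[, 2], norm[, 1], tolerance = 1e-9, ignore_attr = TRUE)

  # a sample already at the cohort anchor mean is unchanged
  flat <- matrix(3, 10, 3, dimnames = list(sprintf("g%d", 1:10),
                                           sprintf("s%d", 1:3)))
  expect_equal(compartment_normalize(flat, rownames(flat)), flat)
  expect_error(compartment_normalize(m, "nope"), "compartment genes")
})

test_that("margin classifier separates planted classes and calibrates scores", {
  set.seed(19)
  n_per <- 20
  m <- matrix(rnorm(50 * 2 * n_per), 50, 2 * n_per,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:(2 * n_per))))
  m[1:10, seq_len(n_per)] <- m[1:10, seq_len(n_per)] + 3
  labels <- rep(c("mesenchymal", "non_mesenchymal"), each = n_per)

  model <- train_margin_classifier(m, labels == "mesenchymal", cost = 1)
  pred <- classify_margin(model, m)
  expect_true(all(pred$score > 0 & pred$score < 1))
  expect_equal(mean((pred$label == "positive") == (labels == "mesenchymal")), 1)

  # label flip negates weights and mirrors scores
  flipped <- train_margin_classifier(m, labels != "mesenchymal", cost = 1)
  expect_equal(unname(flipped$weights), -unname(model$weights), tolerance = 1e-6)
  pred_f <- classify_margin(flipped, m)
  expect_equal(pred_f$score, 1 - pred$score, tolerance = 1e-4)

  # held-out generalization at strong effect
  test_m <- matrix(rnorm(50 * 2 * n_per), 50, 2 * n_per,
                   dimnames = list(rownames(m), sprintf("t%02d", 1:(2 * n_per))))
  test_m[1:10, seq_len(n_per)] <- test_m[1:10, seq_len(n_per)] + 3
  pred_t <- classify_margin(model, test_m)
  expect_gte(mean((pred_t$label == "positive") == rep(c(TRUE, FALSE), each = n_per)),
             0.9)

  # exclusion list removes samples from training
  excl <- train_margin_classifier(m, labels == "mesenchymal",
                                  exclude_samples = colnames(m)[1:2])
  expect_equal(length(excl$genes), 50)
  expect_error(train_margin_classifier(m, rep(TRUE, ncol(m))), "two levels|classes")
})

test_that("dual compartment classifiers recover planted mesenchymal truth", {
  set.seed(20)
  sim <- simulate_pdx_pairs(pdx_sim_spec(n_pdx = 24, n_genes = 500,
                                         n_epithelial_exclusive = 40,
                                         n_stromal_exclusive = 40, seed = 23))
  comp <- compartment_expression(sim$pairs, sim$homology)
  mes <- rep(c(TRUE, FALSE), each = 12)
  # plant a mesenchymal program in both compartments of the affected models
  epi_marks <- sim$truth$epithelial[1:20]
  str_marks <- sim$truth$stromal[1:20]
  human <- comp$human
  mouse <- comp$mouse
  human[epi_marks, mes] <- human[epi_marks, mes] + 3
  mouse[str_marks, mes] <- mouse[str_marks, mes] + 3

  epi_model <- train_margin_classifier(human[sim$truth$epithelial, ], mes)
  str_model <- train_margin_classifier(mouse[sim$truth$stromal, ], mes)
  acc_epi <- mean((classify_margin(epi_model, human[sim$truth$epithelial, ])$label ==
                     "positive") == mes)
  acc_str <- mean((classify_margin(str_model, mouse[sim$truth$stromal, ])$label ==
                     "positive") == mes)
  expect_gte(acc_epi, 0.85)
  expect_gte(acc_str, 0.85)
})
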