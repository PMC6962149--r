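#' Specify a synthetic PDAC-like cohort
#'
#' Bundles the generator parameters for [simulate_cohort()]. Defaults emulate
#' the discovery setting the pipeline targets: ~90 resected PDAC samples with
#' four latent molecular subtypes, subtype-specific signature genes on the
#' log2 RPKM scale, three sequencing batches, and subtype-linked overall
#' survival with medians of 14.7, 31.8, 21.5 and 14.0 months.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes.
#' @param k_subtypes Number of latent subtypes.
#' @param genes_per_signature Signature genes planted per subtype (disjoint
#'   across subtypes).
#' @param signature_effect Additive log2-expression shift of a subtype's
#'   signature genes within that subtype.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param batch_count Number of sequencing batches; 1 disables batch effects.
#' @param batch_shift Additive log2 location shift between consecutive batches.
#' @param subtype_median_os Median overall survival per subtype, months.
#' @param censor_rate Fraction of samples independently censored.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#'
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 90L,
                        n_genes = 8000L,
                        k_subtypes = 4L,
                        genes_per_signature = 40L,
                        signature_effect = 3,
                        noise_sd = 1,
                        batch_count = 3L,
                        batch_shift = 0.5,
                        subtype_median_os = c(14.7, 31.8, 21.5, 14.0),
                        censor_rate = 0.1,
                        seed = 1L) {
  spec <- list(
    n_samples = stopifnot_count(n_samples, "n_samples"),
    n_genes = stopifnot_count(n_genes, "n_genes"),
    k_subtypes = stopifnot_count(k_subtypes, "k_subtypes"),
    genes_per_signature = stopifnot_count(genes_per_signature, "genes_per_signature", min = 0L),
    signature_effect = signature_effect,
    noise_sd = noise_sd,
    batch_count = stopifnot_count(batch_count, "batch_count"),
    batch_shift = batch_shift,
    subtype_median_os = as.numeric(subtype_median_os),
    censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  if (spec$n_samples < spec$k_subtypes) {
    abort("invalid cohort_spec: n_samples must be >= k_subtypes")
  }
  if (spec$genes_per_signature * spec$k_subtypes > spec$n_genes) {
    abort("invalid cohort_spec: genes_per_signature * k_subtypes must be <= n_genes")
  }
  if (length(spec$subtype_median_os) != spec$k_subtypes ||
      any(!is.finite(spec$subtype_median_os)) || any(spec$subtype_median_os <= 0)) {
    abort("invalid cohort_spec: subtype_median_os needs one positive entry per subtype")
  }
  if (spec$censor_rate < 0 || spec$censor_rate > 1) {
    abort("invalid cohort_spec: censor_rate must lie in [0, 1]")
  }
  if (spec$noise_sd < 0) {
    abort("invalid cohort_spec: noise_sd must be non-negative")
  }
  structure(spec, class = "cohort_spec")
}

#' Simulate a synthetic expression cohort with latent subtypes
#'
#' Generates log2-RPKM-scale expression directly (Gaussian noise around
#' per-gene baselines), plants disjoint subtype signatures as additive shifts,
#' applies an additive per-batch location shift, and draws per-subtype
#' exponential survival with independent censoring. Censored samples report a
#' uniformly drawn fraction of their latent survival time.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A `synthetic_cohort` list with elements `expression` (genes x
#'   samples matrix), `truth_labels` (tibble `sample_id`, `label`), `clinical`
#'   (tibble with `sample_id`, `subtype_truth`, `batch`, `os_months`, `event`,
#'   `sex`, `age`), `signature_genes` (named list of per-subtype gene ids) and
#'   `batches` (named character vector).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_samples = 24, n_genes = 400, seed = 7))
#' dim(cohort$expression)
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  with_seed(spec$seed, {
    n <- spec$n_samples
    g <- spec$n_genes
    k <- spec$k_subtypes
    sample_ids <- sprintf("S%03d", seq_len(n))
    gene_ids <- sprintf("G%05d", seq_len(g))

    # Balanced-as-possible subtype assignment in random order.
    subtype_levels <- paste0("PDACS", seq_len(k))
    labels <- sample(rep_len(subtype_levels, n))
    names(labels) <- sample_ids

    # Baseline gene means on the log2 RPKM scale; most genes clear the
    # mean > 1 retention threshold, a tail does not.
    baseline <- rnorm(g, mean = 2.5, sd = 1.5)
    expr <- matrix(rnorm(g * n, sd = spec$noise_sd), nrow = g,
                   dimnames = list(gene_ids, sample_ids)) + baseline

    # Disjoint signature blocks, one per subtype.
    signature_genes <- list()
    if (spec$genes_per_signature > 0) {
      chosen <- sample(gene_ids, spec$genes_per_signature * k)
      signature_genes <- split(chosen, rep(subtype_levels, each = spec$genes_per_signature))
      for (s in subtype_levels) {
        expr[signature_genes[[s]], labels == s] <-
          expr[signature_genes[[s]], labels == s] + spec$signature_effect
      }
    }

    batches <- sample(rep_len(paste0("batch", seq_len(spec$batch_count)), n))
    names(batches) <- sample_ids
    if (spec$batch_count > 1 && spec$batch_shift != 0) {
      shift <- (match(batches, paste0("batch", seq_len(spec$batch_count))) - 1) * spec$batch_shift
      expr <- expr + rep(shift, each = g)
    }

    # Exponential survival with the specified per-subtype medians.
    rate <- log(2) / spec$subtype_median_os[match(labels, subtype_levels)]
    t_true <- rexp(n, rate = rate)
    event <- rbinom(n, 1L, 1 - spec$censor_rate)
    os <- ifelse(event == 1L, t_true, runif(n) * t_true)

    clinical <- tibble(
      sample_id = sample_ids,
      subtype_truth = labels,
      batch = unname(batches),
      os_months = os,
      event = as.integer(event),
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4)),
      age = round(rnorm(n, 66, 8))
    )

    structure(
      list(
        expression = expr,
        truth_labels = tibble(sample_id = sample_ids, label = unname(labels)),
        clinical = clinical,
        signature_genes = signature_genes,
        batches = batches,
        spec = spec
      ),
      class = "synthetic_cohort"
    )
  })
}

#' Add or remove a planted expression shift
#'
#' Adjusts one gene's expression by `delta` log2 units in the samples of one
#' subtype. Because the generator's signals are additive, `delta = -effect`
#' exactly un-plants a signature gene and positive `delta` plants a new or
#' shared marker — useful for constructing signatures whose per-subtype gene
#' lists overlap.
#'
#' @param cohort A `synthetic_cohort`.
#' @param gene Gene identifier.
#' @param subtype Subtype whose samples are shifted.
#' @param delta Log2 shift to add.
#'
#' @return The modified cohort.
#' @export
plant_gene_shift <- function(cohort, gene, subtype, delta) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!gene %in% rownames(cohort$expression)) {
    abort(sprintf("gene '%s' not present in the cohort", gene))
  }
  idx <- cohort$truth_labels$label == subtype
  if (!any(idx)) abort(sprintf("subtype '%s' has no samples", subtype))
  cohort$expression[gene, cohort$truth_labels$sample_id[idx]] <-
    cohort$expression[gene, cohort$truth_labels$sample_id[idx]] + delta
  cohort
}

#' Specify a synthetic species-split PDX batch
#'
#' Parameters for [simulate_pdx_pairs()]. Defaults emulate a set of 14
#' patient-derived xenografts whose reads are species-assigned to the human
#' (tumor) and mouse (stromal) compartments, with compartment-exclusive marker
#' genes planted in each.
#'
#' @param n_pdx Number of xenografts.
#' @param n_genes Number of human genes in the universe.
#' @param n_epithelial_exclusive Genes expressed only in the human compartment.
#' @param n_stromal_exclusive Genes expressed only in the mouse compartment.
#' @param human_fraction_range Interval the per-sample human read fraction is
#'   drawn from (uniform).
#' @param count_noise_sdlog Lognormal gene-by-sample noise on expected counts;
#'   0 gives deterministic expected counts (noise-free).
#' @param homolog_rate Fraction of human genes with a mouse homolog.
#' @param seed Integer seed.
#'
#' @return A `pdx_sim_spec` list.
#' @export
pdx_sim_spec <- function(n_pdx = 14L,
                         n_genes = 4000L,
                         n_epithelial_exclusive = 150L,
                         n_stromal_exclusive = 150L,
                         human_fraction_range = c(0.5, 0.9),
                         count_noise_sdlog = 0.3,
                         homolog_rate = 0.95,
                         seed = 1L) {
  spec <- list(
    n_pdx = stopifnot_count(n_pdx, "n_pdx"),
    n_genes = stopifnot_count(n_genes, "n_genes"),
    n_epithelial_exclusive = stopifnot_count(n_epithelial_exclusive, "n_epithelial_exclusive", 0L),
    n_stromal_exclusive = stopifnot_count(n_stromal_exclusive, "n_stromal_exclusive", 0L),
    human_fraction_range = as.numeric(human_fraction_range),
    count_noise_sdlog = count_noise_sdlog,
    homolog_rate = homolog_rate,
    seed = as.integer(seed)
  )
  if (spec$n_epithelial_exclusive + spec$n_stromal_exclusive > spec$n_genes) {
    abort("invalid pdx_sim_spec: exclusive gene counts exceed n_genes")
  }
  r <- spec$human_fraction_range
  if (length(r) != 2 || any(r <= 0) || any(r >= 1) || r[1] > r[2]) {
    abort("invalid pdx_sim_spec: human_fraction_range must be within (0, 1)")
  }
  structure(spec, class = "pdx_sim_spec")
}

#' Simulate species-assigned PDX count pairs
#'
#' For each xenograft, draws a human read fraction from
#' `human_fraction_range`, gives every gene an expected total count from a
#' fixed lognormal abundance profile (times optional per-sample noise), and
#' splits it between the human- and mouse-mapped vectors: shared genes split
#' exactly by the sample's human fraction before integer rounding,
#' epithelial-exclusive genes land only in the human vector, stromal-exclusive
#' genes only in the mouse vector. Mouse genes are the best homologs of the
#' mapped human genes (prefixed identifiers); a fixed fraction of human genes
#' is left unmapped.
#'
#' @param spec A [pdx_sim_spec()].
#'
#' @return A list with `pairs` (list of `pdx_sample_pair`s, each with
#'   `sample_id`, `human_counts`, `mouse_counts`), `homology` (tibble
#'   `human_gene`, `mouse_gene`, `one_to_one`, `identity`), `truth` (list with
#'   `epithelial` and `stromal` planted gene ids) and `human_fractions`.
#' @export
simulate_pdx_pairs <- function(spec = pdx_sim_spec()) {
  if (!inherits(spec, "pdx_sim_spec")) spec <- do.call(pdx_sim_spec, spec)
  with_seed(spec$seed, {
    g <- spec$n_genes
    gene_ids <- sprintf("HG%05d", seq_len(g))
    excl <- sample(gene_ids, spec$n_epithelial_exclusive + spec$n_stromal_exclusive)
    epithelial <- head(excl, spec$n_epithelial_exclusive)
    stromal <- setdiff(excl, epithelial)

    # Abundance weights; exclusive markers are pinned to a moderate share of
    # the library (10-40 RPM) so their per-compartment log2 RPM falls inside
    # the compartment-selection rule bands at any n_genes.
    lambda <- stats::rlnorm(g, meanlog = log(100), sdlog = 1)
    names(lambda) <- gene_ids
    bg_mass <- sum(lambda[setdiff(gene_ids, excl)])
    if (bg_mass == 0) bg_mass <- 100 * g
    lambda[excl] <- runif(length(excl), 10, 40) * bg_mass / 1e6

    # Homology: every compartment-exclusive gene is mapped (stromal counts
    # live on the mouse side and the compartment universe is homolog-mapped);
    # other genes mapped at homolog_rate.
    mapped <- union(excl, sample(gene_ids, round(spec$homolog_rate * g)))
    homology <- tibble(
      human_gene = sort(mapped),
      mouse_gene = paste0("m", sort(mapped)),
      one_to_one = TRUE,
      identity = round(runif(length(mapped), 85, 100), 1)
    )
    mouse_of <- setNames(homology$mouse_gene, homology$human_gene)

    fr <- runif(spec$n_pdx, spec$human_fraction_range[1], spec$human_fraction_range[2])
    sample_ids <- sprintf("PDX%02d", seq_len(spec$n_pdx))
    names(fr) <- sample_ids

    pairs <- lapply(seq_len(spec$n_pdx), function(i) {
      noise <- if (spec$count_noise_sdlog > 0) {
        stats::rlnorm(g, sdlog = spec$count_noise_sdlog)
      } else {
        rep(1, g)
      }
      total <- lambda * noise * 100 # library depth scaling
      f <- fr[i]
      # Shared genes split exactly by the sample's human fraction (rounding is
      # the only distortion); exclusive genes carry their whole mass on one side.
      human <- round(f * total)
      mouse_share <- round((1 - f) * total)
      human[epithelial] <- round(total[epithelial])
      mouse_share[epithelial] <- 0
      human[stromal] <- 0
      mouse_share[stromal] <- round(total[stromal])
      # mouse share of human genes without an annotated homolog still exists in
      # the stroma; it lands on unpaired mouse gene ids so read totals balance
      unmapped <- setdiff(gene_ids, names(mouse_of))
      mouse <- setNames(rep(0, nrow(homology) + length(unmapped)),
                        c(homology$mouse_gene, paste0("mOrph", unmapped)))
      keep <- intersect(names(mouse_of), gene_ids)
      mouse[mouse_of[keep]] <- mouse_share[keep]
      mouse[paste0("mOrph", unmapped)] <- mouse_share[unmapped]
      structure(
        list(
          sample_id = sample_ids[i],
          human_counts = human,
          mouse_counts = mouse
        ),
        class = "pdx_sample_pair"
      )
    })

    list(
      pairs = pairs,
      homology = homology,
      truth = list(epithelial = sort(epithelial), stromal = sort(stromal)),
      human_fractions = fr,
      spec = spec
    )
  })
}

#' Simulate a second subtyping system from a truth labeling
#'
#' Each sample keeps its original subtype with probability `agreement`,
#' otherwise it is reassigned uniformly among the other subtypes. The label
#' vocabulary is renamed (with a seeded permutation of the class order) so the
#' result looks like an independent classification system.
#'
#' @param truth A labeling (tibble with `sample_id`, `label`, or named vector).
#' @param agreement Probability of keeping the original subtype, in \[0, 1\].
#' @param seed Integer seed.
#' @param prefix Name prefix for the renamed subtypes.
#'
#' @return A tibble `sample_id`, `label`.
#' @export
simulate_alternative_labeling <- function(truth, agreement, seed = 1L, prefix = "Sys") {
  truth <- as_labeling(truth, "truth")
  if (agreement < 0 || agreement > 1) abort("`agreement` must lie in [0, 1]")
  lev <- sort(unique(truth$label))
  with_seed(seed, {
    perm <- sample(length(lev))
    new_names <- setNames(paste0(prefix, LETTERS[perm]), lev)
    keep <- runif(nrow(truth)) < agreement
    label <- truth$label
    if (length(lev) > 1) {
      label[!keep] <- vapply(label[!keep], function(l) sample(setdiff(lev, l), 1L), character(1))
    }
    tibble(sample_id = truth$sample_id, label = unname(new_names[label]))
  })
}
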