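# Species-split PDX analysis: homolog merging, compartment expression,
# donor-PDX concordance gene selection, compartment gene rules, and the
# binary mesenchymal margin classifier.

#' Species read fractions of PDX sample pairs
#'
#' Fraction of reads assigned to the human (tumor) and mouse (stromal)
#' genome per xenograft.
#'
#' @param pairs A `pdx_sample_pair` or list of them.
#' @return A tibble `sample_id`, `human_fraction`, `mouse_fraction`.
#' @export
species_fraction <- function(pairs) {
  if (inherits(pairs, "pdx_sample_pair")) pairs <- list(pairs)
  purrr::map_dfr(pairs, function(p) {
    h <- sum(p$human_counts)
    m <- sum(p$mouse_counts)
    if (h + m == 0) abort(sprintf("sample '%s' has zero total reads", p$sample_id))
    tibble(sample_id = p$sample_id,
           human_fraction = h / (h + m),
           mouse_fraction = m / (h + m))
  })
}

# Resolve a homology table to a named human -> mouse vector, preferring
# one-to-one pairs, then highest identity; unresolvable entries are dropped.
resolve_homology <- function(homology) {
  stopifnot(all(c("human_gene", "mouse_gene") %in% names(homology)))
  h <- as_tibble(homology)
  if (!"one_to_one" %in% names(h)) h$one_to_one <- TRUE
  if (!"identity" %in% names(h)) h$identity <- 100
  h <- h |>
    dplyr::arrange(.data$human_gene, dplyr::desc(.data$one_to_one),
                   dplyr::desc(.data$identity)) |>
    dplyr::distinct(.data$human_gene, .keep_all = TRUE)
  setNames(h$mouse_gene, h$human_gene)
}

# Raw combined (human + homologous mouse) counts on the human gene universe.
combined_counts <- function(pairs, homology) {
  if (inherits(pairs, "pdx_sample_pair")) pairs <- list(pairs)
  map <- resolve_homology(homology)
  if (anyDuplicated(map)) {
    warn("some mouse genes are the homolog of several human genes; their counts are reused")
  }
  genes <- sort(unique(unlist(lapply(pairs, function(p) names(p$human_counts)))))
  counts <- vapply(pairs, function(p) {
    human <- setNames(rep(0, length(genes)), genes)
    human[names(p$human_counts)] <- p$human_counts
    mouse <- rep(0, length(genes))
    mapped <- genes %in% names(map)
    hit <- map[genes[mapped]] %in% names(p$mouse_counts)
    mouse[which(mapped)[hit]] <- p$mouse_counts[map[genes[mapped]][hit]]
    human + mouse
  }, numeric(length(genes)))
  counts <- matrix(counts, nrow = length(genes),
                   dimnames = list(genes, vapply(pairs, `[[`, "", "sample_id")))
  counts
}

#' Combine human and mouse PDX expression into one profile per gene
#'
#' Sums the human-mapped counts of each human gene with the mouse-mapped
#' counts of its best mouse homolog (zero when unmapped), normalizes each
#' sample to reads per million over the combined genes, and returns
#' `log2(RPM + 1)`.
#'
#' @param pairs List of `pdx_sample_pair`s.
#' @param homology Homology table (`human_gene`, `mouse_gene`, optional
#'   `one_to_one`, `identity`).
#'
#' @return A genes x samples matrix on the log2 RPM scale (human gene ids).
#' @export
combine_expression <- function(pairs, homology) {
  counts <- combined_counts(pairs, homology)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort(sprintf("sample(s) with zero combined reads: %s",
                  paste(colnames(counts)[lib == 0], collapse = ", ")))
  }
  rpm <- sweep(counts, 2L, lib, "/") * 1e6
  out <- log2(rpm + 1)
  attr(out, "scale_tag") <- "rpm_log2"
  out
}

#' Per-compartment PDX expression on the merged gene universe
#'
#' The human-mapped (epithelial/tumor) and mouse-mapped (stromal) counts,
#' each indexed by human gene id via the homology map and normalized to
#' log2(RPM + 1) within its own compartment.
#'
#' @inheritParams combine_expression
#' @return A list with matrices `human` and `mouse`.
#' @export
compartment_expression <- function(pairs, homology) {
  if (inherits(pairs, "pdx_sample_pair")) pairs <- list(pairs)
  map <- resolve_homology(homology)
  genes <- sort(unique(unlist(lapply(pairs, function(p) names(p$human_counts)))))
  # the compartment universe is the homolog-mapped genes: a human gene with no
  # mouse homolog cannot be told apart from a tumor-exclusive one
  genes <- intersect(genes, names(map))
  sample_ids <- vapply(pairs, `[[`, "", "sample_id")
  side <- function(getter) {
    m <- vapply(pairs, getter, numeric(length(genes)))
    m <- matrix(m, nrow = length(genes), dimnames = list(genes, sample_ids))
    lib <- colSums(m)
    if (any(lib == 0)) {
      abort(sprintf("sample(s) with zero reads in one compartment: %s",
                    paste(sample_ids[lib == 0], collapse = ", ")))
    }
    log2(sweep(m, 2L, lib, "/") * 1e6 + 1)
  }
  human <- side(function(p) {
    v <- setNames(rep(0, length(genes)), genes)
    hit <- intersect(genes, names(p$human_counts))
    v[hit] <- p$human_counts[hit]
    v
  })
  mouse <- side(function(p) {
    v <- setNames(rep(0, length(genes)), genes)
    mapped <- genes %in% names(map)
    hit <- map[genes[mapped]] %in% names(p$mouse_counts)
    v[which(mapped)[hit]] <- p$mouse_counts[map[genes[mapped]][hit]]
    v
  })
  list(human = human, mouse = mouse)
}

#' Donor-PDX concordant gene selection (correlation of correlations)
#'
#' For every shared gene, its correlation profile against all other shared
#' genes is computed within the donor cohort and within the PDX cohort; the
#' gene's coefficient is the Pearson correlation between the two profiles.
#' Stage 1 keeps genes with coefficient above `coeff_min`; stage 2 further
#' requires a per-dataset standard deviation above `sd_min` in both datasets.
#'
#' @param donor_expr,pdx_expr genes x samples matrices (log scale) with >= 3
#'   samples each.
#' @param coeff_min Correlation-of-correlations threshold.
#' @param sd_min Per-dataset standard-deviation threshold.
#'
#' @return A tibble `gene_id`, `coefficient`, `sd_donor`, `sd_pdx`,
#'   `pass_coefficient`, `selected` over the shared genes.
#' @export
correlation_of_correlations <- function(donor_expr, pdx_expr,
                                        coeff_min = 0.25, sd_min = 1.7) {
  check_expr(donor_expr, "donor_expr")
  check_expr(pdx_expr, "pdx_expr")
  if (ncol(donor_expr) < 3 || ncol(pdx_expr) < 3) {
    abort("need at least 3 samples per dataset")
  }
  shared <- sort(intersect(rownames(donor_expr), rownames(pdx_expr)))
  if (length(shared) < 3) abort("need at least 3 shared genes")
  d <- donor_expr[shared, , drop = FALSE]
  p <- pdx_expr[shared, , drop = FALSE]
  cd <- suppressWarnings(cor(t(d)))
  cp <- suppressWarnings(cor(t(p)))
  coeff <- vapply(seq_along(shared), function(i) {
    a <- cd[i, -i]
    b <- cp[i, -i]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }, numeric(1))
  sd_d <- apply(d, 1L, sd)
  sd_p <- apply(p, 1L, sd)
  tibble(
    gene_id = shared,
    coefficient = coeff,
    sd_donor = unname(sd_d),
    sd_pdx = unname(sd_p),
    pass_coefficient = !is.na(coeff) & coeff > coeff_min,
    selected = !is.na(coeff) & coeff > coeff_min & sd_d > sd_min & sd_p > sd_min
  )
}

#' Select compartment-specific genes from species-split expression
#'
#' Per gene, the minimum and maximum log2 expression across samples is taken
#' in the epithelial (human-mapped) and stromal (mouse-mapped) compartments,
#' and the selection rules applied:
#' epithelial = `(min.ep > 1.5 & max.str < 1.5 & min.ep - max.str > 1.25) |
#' (min.ep - max.str > 5)`; stromal = `(min.str > 1.5 & max.ep < 1.5 &
#' min.str - max.ep > 1.25)` plus a second clause that is
#' `min.ep - max.str > 8` under `stromal_rule = "as_written"` (the default)
#' or the mirrored `min.str - max.ep > 8` under `"symmetric"`. Genes
#' matching both rule sets are dropped with a warning.
#'
#' @param human_expr,mouse_expr genes x samples matrices on the same
#'   (homolog-merged) gene universe, log2 scale.
#' @param stromal_rule Which second stromal clause to apply (see above).
#'
#' @return A list with character vectors `epithelial` and `stromal`.
#' @export
select_compartment_genes <- function(human_expr, mouse_expr,
                                     stromal_rule = c("as_written", "symmetric")) {
  check_expr(human_expr, "human_expr")
  check_expr(mouse_expr, "mouse_expr")
  stromal_rule <- match.arg(stromal_rule)
  if (!identical(rownames(human_expr), rownames(mouse_expr))) {
    shared <- intersect(rownames(human_expr), rownames(mouse_expr))
    if (length(shared) == 0) abort("the matrices share no genes")
    human_expr <- human_expr[shared, , drop = FALSE]
    mouse_expr <- mouse_expr[shared, , drop = FALSE]
  }
  min_ep <- apply(human_expr, 1L, min)
  max_ep <- apply(human_expr, 1L, max)
  min_str <- apply(mouse_expr, 1L, min)
  max_str <- apply(mouse_expr, 1L, max)

  epithelial <- (min_ep > 1.5 & max_str < 1.5 & (min_ep - max_str) > 1.25) |
    (min_ep - max_str) > 5
  stromal_second <- if (stromal_rule == "as_written") {
    (min_ep - max_str) > 8
  } else {
    (min_str - max_ep) > 8
  }
  stromal <- (min_str > 1.5 & max_ep < 1.5 & (min_str - max_ep) > 1.25) |
    stromal_second

  both <- epithelial & stromal
  if (any(both)) {
    warn(sprintf("%d gene(s) matched both compartment rules and were dropped",
                 sum(both)))
    epithelial <- epithelial & !both
    stromal <- stromal & !both
  }
  list(
    epithelial = rownames(human_expr)[epithelial],
    stromal = rownames(human_expr)[stromal]
  )
}

#' Normalize samples against a compartment-specific gene set
#'
#' Shifts every sample (log2 scale) so its mean expression over the
#' compartment gene set equals the cohort-wide mean of that set, removing
#' per-sample tumor/stroma dilution as a location effect.
#'
#' @param expr genes x samples matrix (log2 scale).
#' @param compartment_genes Genes anchoring the normalization.
#'
#' @return The shifted matrix.
#' @export
compartment_normalize <- function(expr, compartment_genes) {
  check_expr(expr)
  genes <- intersect(unique(compartment_genes), rownames(expr))
  if (length(genes) == 0) abort("no compartment genes present in `expr`")
  anchor <- colMeans(expr[genes, , drop = FALSE])
  target <- mean(anchor)
  sweep(expr, 2L, anchor - target, "-")
}

#' Train a linear maximum-margin (SVM) subtype classifier
#'
#' Fits a linear-kernel support vector machine separating the positive class
#' (second sorted level, e.g. mesenchymal) from the rest, then calibrates a
#' monotone sigmoid on the training decision values (Platt-style, with
#' smoothed targets) to map decision values to probability scores in (0, 1).
#'
#' @param expr genes x samples matrix.
#' @param binary_labels Logical or two-level labels; `TRUE`/second level is
#'   the positive class.
#' @param cost SVM cost parameter.
#' @param exclude_samples Sample ids to drop before training (e.g. PDX donor
#'   patients, to avoid bias).
#'
#' @return A `margin_classifier` with fields `genes`, `weights`, `bias`,
#'   `cost_parameter`, `calibration` (intercept and slope of the sigmoid),
#'   `classes` (negative, positive).
#' @export
train_margin_classifier <- function(expr, binary_labels, cost = 1,
                                    exclude_samples = NULL) {
  check_expr(expr)
  if (!is.null(names(binary_labels))) binary_labels <- binary_labels[colnames(expr)]
  pos <- as_binary_groups(binary_labels, ncol(expr))
  if (!is.null(exclude_samples)) {
    keep <- !colnames(expr) %in% exclude_samples
    expr <- expr[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  if (sum(pos) < 2 || sum(!pos) < 2) abort("both classes need at least 2 samples")
  classes <- if (is.logical(binary_labels)) c("negative", "positive") else
    sort(unique(as.character(binary_labels)))

  y <- factor(ifelse(pos, classes[2], classes[1]), levels = classes)
  fit <- e1071::svm(x = t(expr), y = y, kernel = "linear", cost = cost,
                    scale = FALSE, probability = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  # e1071 decision values are oriented toward the first observed class; flip
  # so positive decision values mean the positive class.
  dv <- drop(t(expr) %*% w) - fit$rho
  if (cor(dv, as.numeric(pos)) < 0) {
    w <- -w
    dv <- -dv
    rho <- fit$rho
    bias <- rho
  } else {
    bias <- -fit$rho
  }
  # Platt calibration with smoothed targets, fit by IRLS on the decision value.
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  target <- ifelse(pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  cal <- suppressWarnings(glm(target ~ dv, family = stats::quasibinomial()))

  structure(
    list(
      genes = rownames(expr),
      weights = setNames(w, rownames(expr)),
      bias = bias,
      cost_parameter = cost,
      calibration = setNames(coef(cal), c("intercept", "slope")),
      classes = classes
    ),
    class = "margin_classifier"
  )
}

#' Classify samples with a linear margin classifier
#'
#' @param model A `margin_classifier`.
#' @param expr genes x samples matrix containing the model genes.
#'
#' @return A tibble `sample_id`, `label`, `score` (probability of the
#'   positive class; the other class's probability is `1 - score`) and
#'   `decision_value`.
#' @export
classify_margin <- function(model, expr) {
  stopifnot(inherits(model, "margin_classifier"))
  check_expr(expr)
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing)) {
    abort(sprintf("expr is missing model gene(s): %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  x <- expr[model$genes, , drop = FALSE]
  dv <- drop(t(x) %*% model$weights) + model$bias
  score <- stats::plogis(model$calibration["intercept"] + model$calibration["slope"] * dv)
  tibble(
    sample_id = colnames(x),
    label = ifelse(score >= 0.5, model$classes[2], model$classes[1]),
    score = unname(score),
    decision_value = unname(dv)
  )
}
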