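# broom-style tidy()/glance() methods for the package's fitted objects.

#' @method tidy gap_curve
#' @export
tidy.gap_curve <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance gap_curve
#' @export
glance.gap_curve <- function(x, ...) {
  tibble(optimal_k = attr(x, "optimal_k"), n_k = nrow(x))
}

#' @method tidy sam_result
#' @export
tidy.sam_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance sam_result
#' @export
glance.sam_result <- function(x, ...) {
  tibble(s0 = attr(x, "s0"), n_permutations = attr(x, "n_permutations"),
         n_genes = nrow(x))
}

#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  m <- x$consensus
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    sample_a = rownames(m)[idx[, 1]],
    sample_b = colnames(m)[idx[, 2]],
    consensus = m[idx]
  )
}

#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  v <- x$consensus[upper.tri(x$consensus)]
  tibble(k = x$k, iterations = x$iterations,
         subsample_fraction = x$subsample_fraction,
         mean_consensus = mean(v), cdf_area = consensus_cdf_area(x))
}

#' @method tidy centroid_classifier
#' @export
tidy.centroid_classifier <- function(x, ...) {
  off <- x$shrunken_offsets
  tibble(
    gene_id = rep(rownames(off), ncol(off)),
    class = rep(colnames(off), each = nrow(off)),
    centroid = as.vector(x$centroids),
    shrunken_offset = as.vector(off)
  )
}

#' @method glance centroid_classifier
#' @export
glance.centroid_classifier <- function(x, ...) {
  tibble(
    n_genes = length(x$signature_genes),
    n_classes = length(x$class_ids),
    shrinkage_threshold = x$shrinkage_threshold,
    n_active_genes = sum(rowSums(abs(x$shrunken_offsets)) > 0),
    cv_error = min(x$cv_error$error)
  )
}

#' @method tidy margin_classifier
#' @export
tidy.margin_classifier <- function(x, ...) {
  tibble(gene_id = names(x$weights), weight = unname(x$weights))
}

#' @method glance margin_classifier
#' @export
glance.margin_classifier <- function(x, ...) {
  tibble(n_genes = length(x$genes), bias = x$bias,
         cost_parameter = x$cost_parameter)
}

#' @method tidy concordance_network
#' @export
tidy.concordance_network <- function(x, ...) {
  x$edges
}

#' @method glance concordance_network
#' @export
glance.concordance_network <- function(x, ...) {
  tibble(n_systems = length(unique(x$nodes$system)), n_nodes = nrow(x$nodes),
         n_edges = nrow(x$edges), alpha = x$alpha)
}

#' @method tidy km_estimate
#' @export
tidy.km_estimate <- function(x, ...) {
  x$curve
}

#' @method glance km_estimate
#' @export
glance.km_estimate <- function(x, ...) {
  x$medians
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(n = fit$n, n_events = fit$nevent,
         concordance = unname(fit$concordance["concordance"]),
         log_likelihood = fit$loglik[2])
}
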