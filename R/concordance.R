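# Cross-classification concordance: hypergeometric enrichment, Jaccard
# similarity, and the subtype network connecting classification systems.

#' Hypergeometric enrichment between two subtype labelings
#'
#' For every subtype pair (a from system A, b from system B) over the shared
#' sample universe, the upper-tail hypergeometric probability of observing at
#' least the seen overlap (`P = Pr[X >= x]`, overrepresentation), with
#' Benjamini-Hochberg adjustment across all pairs.
#'
#' @param labels_a,labels_b Labelings (tibbles `sample_id`, `label` or named
#'   vectors); samples outside the intersection are dropped.
#'
#' @return A list with matrices `p_raw`, `p_bh` (rows: subtypes of A,
#'   columns: subtypes of B), `overlap` counts and `universe` size.
#' @export
hypergeometric_enrichment <- function(labels_a, labels_b) {
  a <- as_labeling(labels_a, "labels_a")
  b <- as_labeling(labels_b, "labels_b")
  shared <- intersect(a$sample_id, b$sample_id)
  if (length(shared) == 0) abort("the labelings share no samples")
  a <- a[match(shared, a$sample_id), ]
  b <- b[match(shared, b$sample_id), ]
  n_univ <- length(shared)
  la <- sort(unique(a$label))
  lb <- sort(unique(b$label))
  overlap <- table(factor(a$label, la), factor(b$label, lb))
  m_a <- rowSums(overlap)
  n_b <- colSums(overlap)
  p <- matrix(NA_real_, length(la), length(lb), dimnames = list(la, lb))
  for (i in seq_along(la)) {
    for (j in seq_along(lb)) {
      # Pr[X >= x] for X ~ Hypergeom(white = m_a, black = N - m_a, drawn = n_b)
      p[i, j] <- phyper(overlap[i, j] - 1, m_a[i], n_univ - m_a[i], n_b[j],
                        lower.tail = FALSE)
    }
  }
  p_bh <- matrix(benjamini_hochberg(as.vector(p)), nrow(p), ncol(p),
                 dimnames = dimnames(p))
  list(p_raw = p, p_bh = p_bh, overlap = unclass(overlap), universe = n_univ)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (monotone in `p`, capped at 1).
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Jaccard similarity coefficient of two sample sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 0 with a warning.
#'
#' @param set_a,set_b Vectors of sample ids.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) {
    warn("both sets are empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(set_a, set_b)) / u
}

#' Build the subtype concordance network
#'
#' Nodes are the subtypes of every classification system (with prevalence =
#' number of samples); candidate edges are all cross-system subtype pairs,
#' tested by upper-tail hypergeometric enrichment over the pairwise-shared
#' sample universe with one joint BH family across all candidates; edges with
#' adjusted P below `alpha` are retained and weighted by the Jaccard
#' coefficient of the two sample sets.
#'
#' @param labelings Named list (>= 2) of labelings; names identify the
#'   classification systems.
#' @param alpha BH-adjusted significance threshold for retaining edges.
#' @param bh_family `"global"` adjusts across all system pairs jointly;
#'   `"per_pair"` adjusts within each pair of systems (heatmap convention).
#'
#' @return A `concordance_network`: list with tibbles `nodes` (`system`,
#'   `subtype`, `prevalence`) and `edges` (`system_a`, `subtype_a`,
#'   `system_b`, `subtype_b`, `jaccard`, `p_raw`, `p_bh`), and `alpha`.
#' @export
build_network <- function(labelings, alpha = 0.001,
                          bh_family = c("global", "per_pair")) {
  bh_family <- match.arg(bh_family)
  if (!is.list(labelings) || length(labelings) < 2) {
    abort("need at least 2 labelings")
  }
  if (is.null(names(labelings)) || any(names(labelings) == "")) {
    names(labelings) <- paste0("system", seq_along(labelings))
  }
  labs <- lapply(labelings, as_labeling)

  nodes <- purrr::map2_dfr(labs, names(labs), function(l, nm) {
    dplyr::count(l, .data$label, name = "prevalence") |>
      dplyr::transmute(system = nm, subtype = .data$label,
                       prevalence = .data$prevalence)
  })

  sys_pairs <- combn(names(labs), 2, simplify = FALSE)
  edges <- purrr::map_dfr(sys_pairs, function(pr) {
    a <- labs[[pr[1]]]
    b <- labs[[pr[2]]]
    enr <- hypergeometric_enrichment(a, b)
    shared <- intersect(a$sample_id, b$sample_id)
    grid <- expand.grid(subtype_a = rownames(enr$p_raw),
                        subtype_b = colnames(enr$p_raw),
                        stringsAsFactors = FALSE)
    grid$jaccard <- vapply(seq_len(nrow(grid)), function(i) {
      jaccard(
        a$sample_id[a$label == grid$subtype_a[i] & a$sample_id %in% shared],
        b$sample_id[b$label == grid$subtype_b[i] & b$sample_id %in% shared]
      )
    }, numeric(1))
    grid$p_raw <- enr$p_raw[cbind(grid$subtype_a, grid$subtype_b)]
    tibble(system_a = pr[1], subtype_a = grid$subtype_a,
           system_b = pr[2], subtype_b = grid$subtype_b,
           jaccard = grid$jaccard, p_raw = grid$p_raw)
  })

  if (bh_family == "global") {
    edges$p_bh <- benjamini_hochberg(edges$p_raw)
  } else {
    edges <- edges |>
      dplyr::group_by(.data$system_a, .data$system_b) |>
      dplyr::mutate(p_bh = benjamini_hochberg(.data$p_raw)) |>
      dplyr::ungroup()
  }
  edges <- dplyr::filter(edges, .data$p_bh < alpha) |>
    dplyr::arrange(.data$system_a, .data$system_b, .data$subtype_a, .data$subtype_b)

  structure(
    list(nodes = nodes, edges = edges, alpha = alpha, bh_family = bh_family),
    class = "concordance_network"
  )
}

#' @export
print.concordance_network <- function(x, ...) {
  cat(sprintf("<concordance_network> %d subtypes across %d systems, %d edges (BH-P < %g)\n",
              nrow(x$nodes), length(unique(x$nodes$system)), nrow(x$edges), x$alpha))
  invisible(x)
}

# igraph view of a concordance network (node attribute prevalence, edge
# attribute jaccard); used by the GraphML writer and the plot method.
as_igraph_network <- function(network) {
  stopifnot(inherits(network, "concordance_network"))
  vertices <- data.frame(
    name = paste(network$nodes$system, network$nodes$subtype, sep = ":"),
    system = network$nodes$system,
    subtype = network$nodes$subtype,
    prevalence = network$nodes$prevalence
  )
  edges <- data.frame(
    from = paste(network$edges$system_a, network$edges$subtype_a, sep = ":"),
    to = paste(network$edges$system_b, network$edges$subtype_b, sep = ":"),
    jaccard = network$edges$jaccard,
    p_bh = network$edges$p_bh
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}
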