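# Readers and writers for the pipeline's plain-text formats. TSV dialect:
# tab-separated, UTF-8, '.' decimal, no quoting, first column the identifier.

#' Read and write expression matrices as TSV
#'
#' Genes in rows, a header of sample ids, first column `gene_id`. Numeric
#' fidelity is at least 15 significant digits; round-tripping a matrix
#' reproduces it exactly within double formatting.
#'
#' @param path File path.
#' @return `read_expression_tsv()`: a genes x samples matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("expression TSV needs a gene_id column plus samples")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) abort(sprintf("duplicate gene identifier '%s'", dup[1]))
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) abort("non-numeric expression values")
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) abort("duplicate sample identifiers")
  m
}

#' @rdname read_expression_tsv
#' @param expr genes x samples matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expr(expr)
  df <- dplyr::bind_cols(tibble(gene_id = rownames(expr)), as_tibble(expr))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      abort(sprintf("malformed GMT line %d: need name and description", i))
    }
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional per-set description (defaults to the name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) abort("gene sets must be named")
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write subtype labelings as two-column TSV
#'
#' Columns `sample_id` and `label` (extra posterior columns are preserved on
#' write and ignored on read).
#'
#' @param path File path.
#' @return `read_labels()`: a tibble `sample_id`, `label`.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    abort("labels TSV needs columns sample_id and label")
  }
  dup <- which(duplicated(df$sample_id))
  if (length(dup)) {
    abort(sprintf("duplicate sample_id '%s' at line %d", df$sample_id[dup[1]],
                  dup[1] + 1L))
  }
  tibble(sample_id = as.character(df$sample_id), label = as.character(df$label))
}

#' @rdname read_labels
#' @param labels Tibble with at least `sample_id` and `label`.
#' @export
write_labels <- function(labels, path) {
  labels <- as_tibble(labels)
  if (!all(c("sample_id", "label") %in% names(labels))) {
    abort("labels need columns sample_id and label")
  }
  readr::write_tsv(labels, path)
  invisible(path)
}

#' Read a human-mouse homology table
#'
#' TSV with columns `human_gene`, `mouse_gene` and optionally `one_to_one`
#' and `identity`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_homology <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("human_gene", "mouse_gene") %in% names(df))) {
    abort("homology TSV needs columns human_gene and mouse_gene")
  }
  as_tibble(df)
}

#' Export a concordance network as GraphML
#'
#' Nodes carry `system`, `subtype` and `prevalence`; edges carry `jaccard`
#' and `p_bh`.
#'
#' @param network A `concordance_network`.
#' @param path File path.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph_network(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Serialize and restore a centroid classifier as JSON
#'
#' @param model A `centroid_classifier`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "centroid_classifier"))
  payload <- list(
    signature_genes = model$signature_genes,
    class_ids = model$class_ids,
    overall_centroid = model$overall_centroid,
    centroids = as.data.frame(model$centroids),
    shrunken_offsets = as.data.frame(model$shrunken_offsets),
    shrinkage_threshold = model$shrinkage_threshold,
    class_priors = model$class_priors,
    pooled_sd = model$pooled_sd,
    s0_pam = model$s0_pam,
    m_k = model$m_k
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) {
    m <- as.matrix(as.data.frame(x))
    rownames(m) <- raw$signature_genes
    m
  }
  structure(
    list(
      signature_genes = raw$signature_genes,
      class_ids = raw$class_ids,
      overall_centroid = setNames(raw$overall_centroid, raw$signature_genes),
      centroids = as_mat(raw$centroids),
      shrunken_offsets = as_mat(raw$shrunken_offsets),
      shrinkage_threshold = raw$shrinkage_threshold,
      class_priors = setNames(raw$class_priors, raw$class_ids),
      pooled_sd = setNames(raw$pooled_sd, raw$signature_genes),
      s0_pam = raw$s0_pam,
      m_k = setNames(raw$m_k, raw$class_ids)
    ),
    class = "centroid_classifier"
  )
}

#' Write a consensus matrix or gap curve as TSV
#'
#' @param result A `consensus_result` or `gap_curve`.
#' @param path File path.
#' @export
write_consensus_tsv <- function(result, path) {
  stopifnot(inherits(result, "consensus_result"))
  df <- dplyr::bind_cols(tibble(sample_id = rownames(result$consensus)),
                         as_tibble(result$consensus))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_consensus_tsv
#' @export
write_gap_tsv <- function(result, path) {
  stopifnot(inherits(result, "gap_curve"))
  readr::write_tsv(as_tibble(result), path)
  invisible(path)
}

#' Write a network edge list as TSV
#'
#' @param network A `concordance_network`.
#' @param path File path.
#' @export
write_edges_tsv <- function(network, path) {
  stopifnot(inherits(network, "concordance_network"))
  readr::write_tsv(network$edges, path)
  invisible(path)
}
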