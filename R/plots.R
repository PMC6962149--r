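# Diagnostic ggplot2 figures for the pipeline's result objects.

#' @method autoplot gap_curve
#' @export
autoplot.gap_curve <- function(object, ...) {
  df <- tidy(object)
  opt <- attr(object, "optimal_k")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$se,
                                          ymax = .data$gap + .data$se)) +
    ggplot2::geom_vline(xintercept = opt, linetype = "dashed", colour = "red3") +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic",
                  title = sprintf("Gap statistic (optimal k = %d)", opt)) +
    ggplot2::theme_minimal()
}

#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  ord <- order(object$labels$label)
  m <- object$consensus[ord, ord]
  df <- tibble(
    a = factor(rep(rownames(m), ncol(m)), levels = rownames(m)),
    b = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    consensus = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix, k = %d", object$k)) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
}

#' Consensus CDF curves across k
#'
#' @param results List of `consensus_result`s from [consensus_cluster()].
#' @return A ggplot.
#' @export
plot_consensus_cdf <- function(results) {
  df <- purrr::map_dfr(results, function(r) {
    dplyr::mutate(consensus_cdf(r), k = factor(r$k))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$cdf,
                                   colour = .data$k)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "consensus index", y = "CDF",
                  title = "Consensus cumulative distribution") +
    ggplot2::theme_minimal()
}

#' @method autoplot km_estimate
#' @export
autoplot.km_estimate <- function(object, ...) {
  df <- object$curve |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(time = c(0, .data$time), surv = c(1, .data$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "overall survival",
                  title = "Kaplan-Meier estimate") +
    ggplot2::theme_minimal()
}

#' @method autoplot concordance_network
#' @export
autoplot.concordance_network <- function(object, ...) {
  g <- as_igraph_network(object)
  set.seed(1L) # layout only
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  key <- paste(nodes$system, nodes$subtype, sep = ":")
  e <- object$edges
  seg <- tibble(
    x = nodes$x[match(paste(e$system_a, e$subtype_a, sep = ":"), key)],
    y = nodes$y[match(paste(e$system_a, e$subtype_a, sep = ":"), key)],
    xend = nodes$x[match(paste(e$system_b, e$subtype_b, sep = ":"), key)],
    yend = nodes$y[match(paste(e$system_b, e$subtype_b, sep = ":"), key)],
    jaccard = e$jaccard
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$jaccard),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$prevalence,
                                     colour = .data$system)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$subtype),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::labs(title = "Subtype concordance network") +
    ggplot2::theme_void()
}
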