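#' Plot the category census of a classification
#'
#' Bar chart of gene counts per specificity category, coloured by major
#' group.
#'
#' @param object A `spec_result` from [classify_all()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spec_result <- function(object, ...) {
  cen <- category_census(object)$categories
  cen$major_group <- factor(major_groups[as.character(cen$category)],
                            levels = c("not_detected", "mixed",
                                       "expressed_in_all", "elevated"))
  ggplot2::ggplot(cen, ggplot2::aes(x = .data$category, y = .data$n,
                                    fill = .data$major_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes", fill = "major group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of pairwise correlations
#'
#' @param object A `cor_result` from [pairwise_correlations()].
#' @param method Which coefficient to show, `"spearman"` (default) or
#'   `"pearson"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cor_result <- function(object, method = c("spearman", "pearson"), ...) {
  method <- match.arg(method)
  m <- attr(object, method)
  df <- as_tibble(as.data.frame.table(m, responseName = "r", stringsAsFactors = FALSE))
  names(df)[1:2] <- c("id_a", "id_b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id_a, y = .data$id_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = method) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Plot the tissue co-enrichment network
#'
#' Simple force-directed rendering: tissue nodes and group (combo) nodes,
#' combo size scaled by gene count.
#'
#' @param object An `enrichment_network` from [build_network()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_network <- function(object, ...) {
  g <- as_igraph_network(object)
  xy <- with_local_seed(1L, igraph::layout_with_fr(g))  # layout only
  nodes <- tibble(
    name = igraph::V(g)$name, kind = igraph::V(g)$kind,
    weight = igraph::V(g)$weight, x = xy[, 1L], y = xy[, 2L])
  eidx <- igraph::as_edgelist(g, names = TRUE)
  edges <- tibble(
    x = nodes$x[match(eidx[, 1L], nodes$name)],
    y = nodes$y[match(eidx[, 1L], nodes$name)],
    xend = nodes$x[match(eidx[, 2L], nodes$name)],
    yend = nodes$y[match(eidx[, 2L], nodes$name)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$kind,
                                     size = pmax(.data$weight, 1))) +
    ggplot2::geom_text(data = dplyr::filter(nodes, .data$kind == "tissue"),
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::labs(size = "genes", colour = NULL) +
    ggplot2::theme_void()
}

#' ROC sketch for a dichotomized marker
#'
#' The single-threshold ROC: (0,0), the operating point
#' (1 - specificity, sensitivity), and (1,1); the shaded trapezoid area is
#' the AUC.
#'
#' @param object An `ihc_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ihc_eval <- function(object, ...) {
  s <- object$stats
  pts <- tibble(fpr = c(0, 1 - s$specificity, 1), tpr = c(0, s$sensitivity, 1))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", s$auc)) +
    ggplot2::theme_minimal()
}
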