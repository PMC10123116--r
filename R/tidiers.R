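#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a multi-task fit into per-gene, per-run test R2
#'
#' @param x An `mtl_fit`.
#' @param ... Unused.
#' @return Tibble `gene_id, run, r2`.
#' @export
tidy.mtl_fit <- function(x, ...) x$r2

#' One-row summary of a multi-task fit
#'
#' @param x An `mtl_fit`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `repeats`, `mean_r2`, `median_r2`.
#' @export
glance.mtl_fit <- function(x, ...) {
  per_gene <- dplyr::summarise(dplyr::group_by(x$r2, .data$gene_id),
                               r2 = mean(.data$r2, na.rm = TRUE), .groups = "drop")
  tibble(n_genes = length(x$gene_ids), repeats = length(x$models),
         mean_r2 = mean(per_gene$r2, na.rm = TRUE),
         median_r2 = stats::median(per_gene$r2, na.rm = TRUE))
}

#' Tidy a regulatory network into its edge list
#'
#' @param x A `regulatory_network`.
#' @param ... Unused.
#' @return Tibble `tf, gene_id, importance, n_rounds_supporting`.
#' @export
tidy.regulatory_network <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("tf", "gene_id", "importance", "n_rounds_supporting")])
}

#' One-row summary of a regulatory network
#'
#' @param x A `regulatory_network`.
#' @param ... Unused.
#' @return Tibble with edge, TF and gene counts and the maximum out-degree.
#' @export
glance.regulatory_network <- function(x, ...) {
  deg <- degree_ranking(x)
  tibble(n_edges = nrow(x), n_tfs = length(unique(x$tf)),
         n_genes = length(unique(x$gene_id)),
         max_degree = if (nrow(deg)) deg$degree[1] else 0L)
}

#' Plot per-gene test R2 of a fit
#'
#' @param object An `mtl_fit`.
#' @param ... Unused.
#' @return A ggplot histogram of per-gene mean test R2.
#' @export
autoplot.mtl_fit <- function(object, ...) {
  per_gene <- dplyr::summarise(dplyr::group_by(object$r2, .data$gene_id),
                               r2 = mean(.data$r2, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(per_gene, ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = expression(test ~ R^2), y = "genes",
                  title = "Per-gene velocity prediction") +
    ggplot2::theme_minimal()
}

#' Plot the TF out-degree distribution of a network
#'
#' @param object A `regulatory_network`.
#' @param top_n Show this many top TFs.
#' @param ... Unused.
#' @return A ggplot bar chart of TF out-degrees.
#' @export
autoplot.regulatory_network <- function(object, top_n = 20, ...) {
  deg <- head(degree_ranking(object), top_n)
  deg$tf <- factor(deg$tf, levels = rev(deg$tf))
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$degree, y = .data$tf)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "out-degree (target genes)", y = NULL,
                  title = "TFs ranked by network degree") +
    ggplot2::theme_minimal()
}
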