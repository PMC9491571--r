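# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_segment
#'   geom_histogram geom_hline geom_vline labs scale_y_log10 theme_minimal
#'   coord_flip
NULL

#' Plot a screen result
#'
#' Histogram of the per-gene median absolute correlation with the selection
#' cutoff marked.
#'
#' @param object A `screen_result`.
#' @param bins Histogram bins.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.screen_result <- function(object, bins = 60, ...) {
  cutoff <- attr(object, "cutoff") %||% 0.2
  ggplot(object, aes(x = .data$median_abs_r)) +
    geom_histogram(bins = bins, fill = "grey35") +
    geom_vline(xintercept = cutoff, linetype = 2, colour = "firebrick") +
    scale_y_log10() +
    labs(x = "median |R| across resamples", y = "genes (log scale)",
         title = sprintf("Reference-gene correlation screen (%d of %d genes > %.2f)",
                         sum(object$selected), nrow(object), cutoff)) +
    theme_minimal()
}

#' Plot a calibration curve
#'
#' False-selection rate of the permutation null as a function of the
#' correlation cutoff.
#'
#' @param object A `calibration_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$cutoff, y = .data$rate)) +
    geom_line(colour = "grey40") +
    geom_point() +
    labs(x = "correlation cutoff", y = "null exceedance rate",
         title = sprintf("Permutation calibration (%s mode, %s permutations)",
                         object$mode[1], format(object$n_permutations[1],
                                                big.mark = ","))) +
    theme_minimal()
}

#' Plot a drug-target network
#'
#' Simple bipartite layout: drugs on the left, genes on the right,
#' prioritized relations highlighted.
#'
#' @param object A `drug_target_network`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.drug_target_network <- function(object, ...) {
  drugs <- sort(unique(object$edges$drug))
  genes <- sort(unique(object$edges$gene))
  pos <- dplyr::bind_rows(
    tibble(node = drugs, x = 0, y = seq_along(drugs)),
    tibble(node = genes, x = 1,
           y = seq_along(genes) * (max(1, length(drugs)) / max(1, length(genes)))))
  seg <- object$edges |>
    left_join(pos |> rename(x0 = "x", y0 = "y"), by = c(drug = "node")) |>
    left_join(pos |> rename(x1 = "x", y1 = "y"), by = c(gene = "node"))
  nodes <- pos |>
    left_join(object$nodes |> select("node", "type", "direction"), by = "node")
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                     colour = .data$prioritized),
                 linewidth = 0.4) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, shape = .data$type), size = 2) +
    ggplot2::geom_text(data = nodes,
                       aes(x = .data$x + ifelse(.data$x == 0, -0.03, 0.03),
                           y = .data$y, label = .data$node,
                           hjust = ifelse(.data$x == 0, 1, 0)), size = 2.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey70")) +
    ggplot2::xlim(-0.6, 1.6) +
    ggplot2::theme_void() +
    labs(title = "Drug-target network", colour = "prioritized")
}

#' Plot enrichment results
#'
#' Bar chart of -log10 q-values for the top pathways.
#'
#' @param records ORA tibble from [ora_hypergeometric()].
#' @param q_threshold Significance threshold to mark.
#' @param top Number of pathways shown.
#' @return A ggplot.
#' @export
plot_enrichment <- function(records, q_threshold = 0.05, top = 20) {
  d <- records |> arrange(.data$q_value) |> head(top)
  ggplot(d, aes(x = stats::reorder(.data$pathway_id, -.data$q_value),
                y = -log10(pmax(.data$q_value, 1e-300)))) +
    geom_col(fill = "grey35") +
    geom_hline(yintercept = -log10(q_threshold), linetype = 2,
               colour = "firebrick") +
    coord_flip() +
    labs(x = NULL, y = "-log10 q-value", title = "Pathway over-representation") +
    theme_minimal()
}
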