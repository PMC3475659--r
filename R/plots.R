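# ggplot2 presentation of the main result types

#' Plot a degree-distribution power-law fit
#'
#' Log-log scatter of the degree histogram with the fitted
#' `P(k) = c k^-gamma` line.
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree k", y = "P(k)",
      title = sprintf("Degree distribution, fitted gamma = %.2f (r² = %.2f)",
                      object$gamma, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a modularity null distribution
#'
#' Histogram of rewired-network modularity ratios with the observed ratio
#' marked.
#'
#' @param object A `modularity_null`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modularity_null <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null_ratio)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_ratio,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(
      x = "modularity ratio (null replicates)", y = "count",
      title = sprintf("Observed %.2f vs null mean %.2f (p = %.3g)",
                      object$observed_ratio, object$null_mean,
                      object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation robustness summary
#'
#' Mean rank with standard deviation per node under edge perturbation,
#' nodes ordered by unperturbed rank, with dashed lines marking the top-10%
#' and top-20% rank cutoffs.
#'
#' @param object A `perturbation_summary`.
#' @param top_fraction Show only the best-ranked fraction of nodes
#'   (default 0.2, mirroring the usual presentation).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perturbation_summary <- function(object, top_fraction = 0.2, ...) {
  n <- nrow(object)
  d <- dplyr::arrange(tibble::as_tibble(object), .data$rank_unperturbed,
                      .data$node)
  d <- utils::head(d, ceiling(top_fraction * n))
  d$node <- factor(d$node, levels = d$node)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node, y = .data$mean_rank)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_rank - .data$sd_rank, 0),
      ymax = .data$mean_rank + .data$sd_rank), width = 0.3) +
    ggplot2::geom_hline(yintercept = ceiling(0.1 * n), colour = "blue",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = ceiling(0.2 * n), colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "mean rank over replicates",
      title = sprintf("%s rank robustness (%s %.0f%%, %d replicates)",
                      attr(object, "rank_by"), attr(object, "model"),
                      100 * attr(object, "fraction"),
                      attr(object, "n_replicates"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot linkerity against neighbour heterogeneity
#'
#' @param linkerity A linkerity table (see [linkerity_table()]).
#' @param profiles A neighbour profile table (see [neighbor_profiles()]).
#' @return A ggplot object (finite heterogeneity ratios only).
#' @export
plot_linkerity_heterogeneity <- function(linkerity, profiles) {
  d <- dplyr::inner_join(linkerity[c("node", "linkerity")],
                         profiles[c("node", "hetero_ratio")], by = "node")
  d <- d[is.finite(d$hetero_ratio), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$linkerity,
                                  y = .data$hetero_ratio)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "linkerity",
                  y = "heterogeneous / homogeneous neighbour ratio") +
    ggplot2::theme_minimal()
}
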