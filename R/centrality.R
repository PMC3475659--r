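#' Betweenness centrality scores
#'
#' Unnormalised shortest-path betweenness on the undirected, unweighted
#' graph: for node v, the sum over node pairs (s, t), both distinct from v,
#' of the fraction of shortest s-t paths passing through v. Endpoints are
#' excluded; when several equally short paths exist, each contributes
#' fractionally. Normalisation is irrelevant downstream because the
#' average-tie ranking is invariant under positive monotone transforms of
#' the scores. The caller normally passes a connected graph (the largest
#' component); with fewer than 3 nodes every score is 0.
#'
#' @param graph An `annotated_graph`.
#' @return A tibble with columns `node`, `score`, in graph vertex order.
#' @export
betweenness_scores <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) return(tibble::tibble(node = character(0), score = numeric(0)))
  sc <- if (n < 3) stats::setNames(rep(0, n), igraph::V(graph)$name) else
    igraph::betweenness(graph, directed = FALSE, weights = NA, normalized = FALSE)
  tibble::tibble(node = igraph::V(graph)$name, score = unname(sc))
}

#' Degree scores
#'
#' @param graph An `annotated_graph`.
#' @return A tibble with columns `node`, `score` (degree).
#' @export
degree_scores <- function(graph) {
  tibble::tibble(node = igraph::V(graph)$name %||% character(0),
                 score = as.numeric(igraph::degree(graph)))
}

#' Average-tie ranking of centrality scores
#'
#' Ranks nodes by score in descending order (rank 1 = highest score), with
#' consecutive nodes of exactly equal score all receiving the arithmetic
#' mean of the integer positions their tie group spans: scores
#' \[10, 10, 7, 5, 5, 5\] rank as \[1.5, 1.5, 3, 5, 5, 5\]. This keeps the
#' ranking well defined in interaction networks where many peripheral nodes
#' share a betweenness of exactly 0. Ranks over n nodes always sum to
#' n(n+1)/2.
#'
#' @param scores A tibble with columns `node` and `score` (as returned by
#'   [betweenness_scores()] or [degree_scores()]), or a named numeric
#'   vector.
#' @return A tibble with columns `node`, `score`, `rank`, sorted by
#'   ascending rank then node identifier. Empty input gives an empty table.
#' @export
#' @examples
#' average_rank(c(A = 10, B = 10, C = 7, D = 5, E = 5, F = 5))
average_rank <- function(scores) {
  if (is.numeric(scores)) {
    scores <- tibble::tibble(node = names(scores) %||%
                               as.character(seq_along(scores)),
                             score = unname(scores))
  }
  abort_if(!all(c("node", "score") %in% names(scores)),
           "`scores` needs columns `node` and `score`")
  abort_if(any(!is.finite(scores$score)), "scores must be finite")
  out <- tibble::as_tibble(scores)[c("node", "score")]
  if (nrow(out) == 0) return(dplyr::mutate(out, rank = numeric(0)))
  out$rank <- rank(-out$score, ties.method = "average")
  dplyr::arrange(out, .data$rank, .data$node)
}

#' Top fraction of a rank table
#'
#' The `ceiling(fraction * n)` best-ranked nodes (smallest rank values). A
#' tie group straddling the boundary is included whole only when it fits;
#' otherwise members are taken in identifier order until the quota is
#' filled. Hubs and bottlenecks are the top 20% by degree and betweenness
#' rank respectively.
#'
#' @param rank_table A tibble with columns `node` and `rank` (see
#'   [average_rank()]).
#' @param fraction Fraction in (0, 1\].
#' @return Character vector of node identifiers.
#' @export
top_fraction <- function(rank_table, fraction) {
  abort_if(!is.numeric(fraction) || fraction <= 0 || fraction > 1,
           "`fraction` must be in (0, 1]")
  k <- ceiling(fraction * nrow(rank_table))
  ordered <- dplyr::arrange(rank_table, .data$rank, .data$node)
  utils::head(ordered$node, k)
}

#' Essentiality enrichment of a node set
#'
#' Percentage of essential (E) genes in a node set, given gene-deletion
#' lethality labels (E = essential, V = viable). Nodes without a label are
#' excluded from the denominator and counted.
#'
#' @param node_set Character vector of node identifiers (e.g. hubs from
#'   [top_fraction()]).
#' @param labels A data frame with columns `node` and `lethality` (values
#'   `"E"`/`"V"`), or a named character vector.
#' @return A one-row tibble: `set_size` (labelled nodes), `n_essential`,
#'   `pct_essential`, `n_unlabelled`.
#' @export
essentiality_enrichment <- function(node_set, labels) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$lethality),
                              as.character(labels$node))
  }
  lab <- labels[node_set]
  covered <- !is.na(lab)
  abort_if(sum(covered) == 0, "no node in `node_set` has a lethality label")
  tibble::tibble(
    set_size = sum(covered),
    n_essential = sum(lab[covered] == "E"),
    pct_essential = 100 * sum(lab[covered] == "E") / sum(covered),
    n_unlabelled = sum(!covered)
  )
}

#' Fit a power law to a degree distribution
#'
#' Least-squares line fit of log P(k) against log k, the classic check that
#' a protein interaction network is scale free: P(k) ~ c k^-gamma. The
#' degree histogram uses one bin per integer degree up to the maximum
#' observed degree; bins with zero frequency are dropped before taking
#' logs (log 0 is undefined). At least 3 positive-frequency bins with k >= 1
#' are required.
#'
#' @param degrees Either a numeric vector of node degrees, or a data frame
#'   with columns `degree` and `frequency` giving a pre-computed histogram.
#' @return A `power_law_fit` object with fields `c` (prefactor), `gamma`
#'   (exponent, > 0 for decaying distributions), `r_squared`, and the
#'   histogram used. Has [tidy()], [glance()] and [ggplot2::autoplot()]
#'   methods.
#' @export
#' @examples
#' h <- tibble::tibble(degree = 1:50, frequency = (1:50)^-2)
#' fit_power_law(h)$gamma
fit_power_law <- function(degrees) {
  if (is.data.frame(degrees)) {
    abort_if(!all(c("degree", "frequency") %in% names(degrees)),
             "histogram needs columns `degree` and `frequency`")
    hist <- tibble::as_tibble(degrees)[c("degree", "frequency")]
  } else {
    degrees <- degrees[degrees >= 1]
    abort_if(length(degrees) == 0, "no positive degrees")
    kmax <- max(degrees)
    hist <- tibble::tibble(
      degree = seq_len(kmax),
      frequency = as.numeric(tabulate(degrees, nbins = kmax)) / length(degrees)
    )
  }
  usable <- hist$frequency > 0 & hist$degree >= 1
  abort_if(sum(usable) < 3,
           "need at least 3 positive-frequency degree bins to fit")
  h <- hist[usable, ]
  fit <- stats::lm(log(frequency) ~ log(degree), data = h)
  structure(
    list(
      c = exp(unname(stats::coef(fit)[1])),
      gamma = -unname(stats::coef(fit)[2]),
      # noiseless histograms fit exactly; summary.lm warns about that
      r_squared = suppressWarnings(summary(fit)$r.squared),
      histogram = h,
      n_bins = nrow(h)
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: P(k) ~ %.4g * k^-%.3f  (r^2 = %.3f, %d bins)\n",
              x$c, x$gamma, x$r_squared, x$n_bins))
  invisible(x)
}
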