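#' Neighbour-annotation profile of a node
#'
#' For a node viewed under one of its functional categories, counts its
#' annotated network neighbours that carry the focal category (`n_same`)
#' and those that carry only other categories (`n_other`), plus the
#' per-category neighbour counts (a multi-annotated neighbour is counted
#' under every category it carries). The heterogeneity ratio
#' `hetero_ratio = n_other / n_same` measures how much a protein interacts
#' outside its own functional group; it is `Inf` (flagged) when all
#' annotated neighbours are foreign, and unannotated neighbours are
#' excluded and counted separately.
#'
#' @param graph An `annotated_graph`.
#' @param node A node identifier carrying `focal_category`.
#' @param focal_category The category under which the node is examined.
#' @return A one-row tibble: `node`, `focal_category`, `n_same`, `n_other`,
#'   `n_unannotated`, `hetero_ratio`, plus one `n_<category>` count column
#'   per category in the graph.
#' @export
neighbor_profile <- function(graph, node, focal_category) {
  names <- igraph::V(graph)$name
  abort_if(!node %in% names, sprintf("node '%s' not in graph", node))
  cats <- node_categories(graph)
  names(cats) <- names
  abort_if(!focal_category %in% cats[[node]],
           sprintf("node '%s' does not carry category '%s'", node,
                   focal_category))
  nbr <- igraph::V(graph)$name[igraph::neighbors(graph, node)]
  nbr_cats <- cats[nbr]
  annotated <- lengths(nbr_cats) > 0
  n_same <- sum(vapply(nbr_cats[annotated],
                       function(x) focal_category %in% x, logical(1)))
  n_other <- sum(annotated) - n_same
  universe <- category_universe(graph)
  per_cat <- vapply(universe, function(cc) {
    sum(vapply(nbr_cats, function(x) cc %in% x, logical(1)))
  }, integer(1))
  out <- tibble::tibble(
    node = node, focal_category = focal_category,
    n_same = n_same, n_other = n_other,
    n_unannotated = sum(!annotated),
    hetero_ratio = if (n_same > 0) n_other / n_same else
      if (n_other > 0) Inf else NaN
  )
  for (cc in universe) out[[paste0("n_", cc)]] <- per_cat[[cc]]
  out
}

#' Neighbour profiles for every member of a category
#'
#' @param graph An `annotated_graph`.
#' @param focal_category Category label.
#' @return A tibble of [neighbor_profile()] rows, one per node carrying the
#'   category.
#' @export
neighbor_profiles <- function(graph, focal_category) {
  cats <- node_categories(graph)
  members <- igraph::V(graph)$name[
    vapply(cats, function(x) focal_category %in% x, logical(1))]
  purrr::map_dfr(members, neighbor_profile, graph = graph,
                 focal_category = focal_category)
}

#' Association between linkerity and neighbour heterogeneity
#'
#' Tests whether high-linkerity proteins interact with a more
#' heterogeneously annotated neighbourhood, by correlating linkerity with
#' the heterogeneity ratio across sub-network members. The default
#' statistic is Spearman's rank correlation (linkerity is itself
#' rank-derived, so only the ordering is meaningful); Pearson is available.
#' Nodes with an infinite or undefined heterogeneity ratio (`n_same = 0`)
#' are excluded and counted.
#'
#' @param linkerity A linkerity table (see [linkerity_table()]).
#' @param profiles A profile table (see [neighbor_profiles()]).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A one-row tibble: `estimate` (correlation coefficient),
#'   `p_value` (two-sided), `n` (paired observations used), `n_excluded`,
#'   `method`.
#' @export
linkerity_heterogeneity_association <- function(linkerity, profiles,
                                                method = c("spearman",
                                                           "pearson")) {
  method <- match.arg(method)
  joined <- dplyr::inner_join(
    linkerity[c("node", "linkerity")],
    profiles[c("node", "hetero_ratio")], by = "node")
  usable <- is.finite(joined$hetero_ratio)
  n_excluded <- sum(!usable)
  joined <- joined[usable, ]
  abort_if(nrow(joined) < 5, "need at least 5 paired finite observations")
  abort_if(stats::sd(joined$linkerity) == 0 ||
             stats::sd(joined$hetero_ratio) == 0,
           "constant vector; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(
    joined$linkerity, joined$hetero_ratio,
    method = method, alternative = "two.sided", exact = FALSE))
  tibble::tibble(
    estimate = unname(ct$estimate),
    p_value = ct$p.value,
    n = nrow(joined),
    n_excluded = n_excluded,
    method = method
  )
}
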