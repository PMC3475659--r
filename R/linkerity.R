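#' Linkerity score
#'
#' The linkerity of a protein is the ratio of its average-tie betweenness
#' rank inside its functional sub-network to its rank among sub-network
#' members evaluated in the merged core network:
#' `linkerity = rank_sub / rank_core`. A protein whose rank does not shift
#' has linkerity 1 by definition; values well above 1 mark proteins that sit
#' at the fringe of their own functional sub-network yet become central once
#' the sub-network is embedded in the larger core — candidate linkers
#' between cellular processes. Values are returned at full precision;
#' [round_display()] gives the conventional 2-decimal presentation.
#'
#' @param rank_sub Betweenness rank(s) in the sub-network (>= 1).
#' @param rank_core Rank(s) in the core network, computed among sub-network
#'   members only (>= 1).
#' @return Numeric vector of linkerity values.
#' @export
#' @examples
#' linkerity_score(73.5, 8)          # 9.1875
#' round_display(linkerity_score(73.5, 8))
linkerity_score <- function(rank_sub, rank_core) {
  abort_if(any(rank_core <= 0), "`rank_core` must be positive")
  abort_if(any(rank_sub <= 0), "`rank_sub` must be positive")
  rank_sub / rank_core
}

#' Rank nodes in the core network, restricted to a member set
#'
#' Betweenness centrality is computed on the full core network (its largest
#' connected component), but only the given member nodes are then sorted and
#' average-ranked among themselves — all other proteins are skipped. This is
#' the `Rank_core` column of a linkerity table. Members absent from the core
#' component are excluded and reported via the `n_excluded` attribute.
#'
#' @param core An `annotated_graph`, the merged core network.
#' @param members Character vector of node identifiers (sub-network members).
#' @return A rank table (tibble: `node`, `score`, `rank`) over the retained
#'   members.
#' @export
rank_in_core <- function(core, members) {
  comp <- largest_component(core)
  present <- members[members %in% igraph::V(comp)$name]
  n_excluded <- length(members) - length(present)
  if (n_excluded > 0) {
    rlang::inform(sprintf(
      "%d member(s) not in the core's largest component were excluded",
      n_excluded))
  }
  bc <- betweenness_scores(comp)
  out <- average_rank(bc[bc$node %in% present, ])
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Linkerity table for one functional category
#'
#' Runs the full linkerity pipeline for one category: extract the induced
#' sub-network of nodes carrying the category, keep its largest connected
#' component, rank members by betweenness within it (`rank_sub`), rank the
#' same members by their betweenness in the core network (`rank_core`, via
#' [rank_in_core()]), and score each member as `rank_sub / rank_core`.
#' Members of the category outside the sub-network's largest component get
#' no record.
#'
#' @param core An `annotated_graph`: the merged multi-category core network
#'   (callers normally pass its largest component).
#' @param category A category label present in the core's annotations.
#' @return A tibble with columns `node`, `categories` (the node's full
#'   category set, `"+"`-joined), `rank_sub`, `rank_core`, `linkerity`,
#'   sorted by descending linkerity, ties by node identifier.
#' @export
linkerity_table <- function(core, category) {
  abort_if(!category %in% category_universe(core),
           sprintf("category '%s' not present in core annotations", category))
  sub <- largest_component(subnetwork(core, category))
  abort_if(igraph::vcount(sub) < 3, sprintf(
    "category '%s' yields %d connected node(s); need >= 3 for betweenness",
    category, igraph::vcount(sub)))
  rank_sub <- average_rank(betweenness_scores(sub))
  rank_core <- rank_in_core(core, rank_sub$node)
  cats <- node_categories(core)
  names(cats) <- igraph::V(core)$name
  out <- rank_sub |>
    dplyr::select(node = "node", rank_sub = "rank") |>
    dplyr::inner_join(dplyr::select(rank_core, node = "node",
                                    rank_core = "rank"),
                      by = "node") |>
    dplyr::mutate(
      categories = vapply(cats[.data$node], paste, character(1),
                          collapse = "+"),
      linkerity = linkerity_score(.data$rank_sub, .data$rank_core)
    ) |>
    dplyr::select("node", "categories", "rank_sub", "rank_core", "linkerity") |>
    dplyr::arrange(dplyr::desc(.data$linkerity), .data$node)
  out
}

#' Linkerity tables for every category
#'
#' @param core An `annotated_graph`.
#' @param categories Category labels (default: all in the core).
#' @return A tibble with a leading `category` column, rows stacked from
#'   [linkerity_table()] per category.
#' @export
linkerity_all <- function(core, categories = category_universe(core)) {
  purrr::map_dfr(categories, function(cat) {
    dplyr::mutate(linkerity_table(core, cat), category = cat,
                  .before = 1)
  })
}
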