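#' k-clique percolation communities
#'
#' Community detection by clique percolation: a community is the union of
#' all k-cliques reachable from one another through chains of k-cliques
#' sharing k-1 nodes. Unlike partitioning methods, communities may overlap
#' — a node can belong to several — which suits protein networks where
#' multifunctional proteins join more than one functional module. The
#' implementation percolates over the graph's maximal cliques of size >= k
#' (two such cliques are adjacent when they share at least k-1 nodes),
#' which yields exactly the k-clique percolation clusters. Structures
#' smaller than a k-clique are not reported.
#'
#' @param graph An `annotated_graph`.
#' @param k Clique size, >= 2 (default 4, the size used for the fission
#'   yeast core network). With `k = 2`, communities are simply the
#'   connected components with at least one edge.
#' @return A `community_set`: a list with `communities` (list of sorted
#'   node-identifier vectors, ordered by smallest member) and `k`. Empty
#'   when the graph has no k-clique.
#' @export
#' @examples
#' g <- build_graph(tibble::tibble(
#'   protein_a = c("a", "a", "a", "b", "b", "c"),
#'   protein_b = c("b", "c", "d", "c", "d", "d")))
#' k_clique_communities(g, k = 3)
k_clique_communities <- function(graph, k = 4) {
  abort_if(!is.numeric(k) || k < 2, "`k` must be >= 2")
  cliques <- igraph::max_cliques(graph, min = k)
  if (length(cliques) == 0) {
    return(structure(list(communities = list(), k = k),
                     class = "community_set"))
  }
  members <- lapply(cliques, function(cl) sort(igraph::V(graph)$name[cl]))
  nc <- length(members)
  # union-find over cliques; adjacency = overlap >= k-1 nodes
  parent <- seq_len(nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nc > 1) {
    for (i in seq_len(nc - 1)) {
      for (j in seq(i + 1, nc)) {
        if (length(intersect(members[[i]], members[[j]])) >= k - 1) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(nc), find, integer(1))
  comms <- lapply(split(seq_len(nc), roots), function(ix) {
    sort(unique(unlist(members[ix])))
  })
  comms <- comms[order(vapply(comms, `[`, character(1), 1))]
  names(comms) <- NULL
  structure(list(communities = comms, k = k), class = "community_set")
}

#' @export
print.community_set <- function(x, ...) {
  cat(sprintf("<community_set> k = %d, %d communit%s\n", x$k,
              length(x$communities),
              if (length(x$communities) == 1) "y" else "ies"))
  for (i in seq_along(x$communities)) {
    cat(sprintf("  [%d] %d nodes: %s\n", i, length(x$communities[[i]]),
                paste(utils::head(x$communities[[i]], 8), collapse = ", ")))
  }
  invisible(x)
}

#' Community membership as a long table
#'
#' @param communities A `community_set`.
#' @return A tibble with columns `community` (integer id) and `node`; nodes
#'   in several communities appear once per community.
#' @export
community_membership <- function(communities) {
  if (length(communities$communities) == 0) {
    return(tibble::tibble(community = integer(0), node = character(0)))
  }
  purrr::imap_dfr(communities$communities, function(nodes, i) {
    tibble::tibble(community = i, node = nodes)
  })
}

#' Functional composition of communities
#'
#' For each community, counts members per exact annotation subset (a member
#' annotated to several categories is counted once, under its full subset)
#' — the numbers behind per-clique functional pie charts.
#'
#' @param communities A `community_set`.
#' @param annotations An annotation table (`node`, `category`) or an
#'   `annotated_graph` carrying the annotations.
#' @return A tibble with `community`, `categories` (subset label,
#'   `"+"`-joined; `"(unannotated)"` for members without categories) and
#'   `n`.
#' @export
community_composition <- function(communities, annotations) {
  membership <- community_membership(communities)
  if (nrow(membership) == 0) {
    return(tibble::tibble(community = integer(0), categories = character(0),
                          n = integer(0)))
  }
  if (inherits(annotations, "annotated_graph")) {
    cats <- node_categories(annotations)
    names(cats) <- igraph::V(annotations)$name
  } else {
    cats <- lapply(split(annotations$category, annotations$node),
                   function(x) sort(unique(x)))
  }
  membership |>
    dplyr::mutate(categories = vapply(.data$node, function(nd) {
      cc <- cats[[nd]]
      if (is.null(cc) || length(cc) == 0) "(unannotated)" else
        paste(sort(cc), collapse = "+")
    }, character(1))) |>
    dplyr::count(.data$community, .data$categories, name = "n")
}
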