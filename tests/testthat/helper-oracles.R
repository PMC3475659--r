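# Independent brute-force oracles. These deliberately avoid igraph's
# algorithms: betweenness is computed by enumerating all shortest paths with
# BFS + recursive path expansion over an adjacency list, components by flood
# fill, and k-clique communities by enumerating every k-subset of nodes.

# adjacency list (named list of character vectors) from an edge tibble
oracle_adjacency <- function(edges, nodes) {
  adj <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# all shortest paths between s and t: BFS distances, then recursive descent
oracle_shortest_paths <- function(adj, s, t) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (is.infinite(dist[t])) return(list())
  # walk back from t along strictly decreasing distance
  descend <- function(v) {
    if (v == s) return(list(s))
    preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
    unlist(lapply(preds, function(p) {
      lapply(descend(p), function(path) c(path, v))
    }), recursive = FALSE)
  }
  descend(t)
}

# unnormalized betweenness: fraction of s-t geodesics through v, summed over
# unordered pairs with s,t != v
oracle_betweenness <- function(graph) {
  edges <- linkerity::graph_edges(graph)
  nodes <- sort(igraph::V(graph)$name)
  adj <- oracle_adjacency(edges, nodes)
  bc <- stats::setNames(rep(0, length(nodes)), nodes)
  if (length(nodes) < 3) return(bc)
  for (i in seq_len(length(nodes) - 1)) {
    for (j in seq(i + 1, length(nodes))) {
      paths <- oracle_shortest_paths(adj, nodes[i], nodes[j])
      if (length(paths) == 0) next
      for (path in paths) {
        inner <- setdiff(path, c(nodes[i], nodes[j]))
        bc[inner] <- bc[inner] + 1 / length(paths)
      }
    }
  }
  bc
}

# connected components by flood fill; list of sorted node vectors
oracle_components <- function(edges, nodes) {
  adj <- oracle_adjacency(edges, nodes)
  unseen <- nodes
  comps <- list()
  while (length(unseen) > 0) {
    frontier <- unseen[1]
    comp <- character(0)
    while (length(frontier) > 0) {
      comp <- union(comp, frontier)
      frontier <- setdiff(unique(unlist(adj[frontier])), comp)
    }
    comps[[length(comps) + 1]] <- sort(comp)
    unseen <- setdiff(unseen, comp)
  }
  comps
}

# k-clique percolation by full enumeration: every k-subset that induces a
# clique is a k-clique; two k-cliques are adjacent iff they share k-1 nodes;
# communities are unions of connected sets of k-cliques
oracle_k_clique_communities <- function(graph, k) {
  nodes <- sort(igraph::V(graph)$name)
  edges <- linkerity::graph_edges(graph)
  ekeys <- paste(edges$from, edges$to)
  is_edge <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% ekeys
  if (length(nodes) < k) return(list())
  subsets <- utils::combn(nodes, k, simplify = FALSE)
  cliques <- Filter(function(ss) {
    prs <- utils::combn(ss, 2)
    all(is_edge(prs[1, ], prs[2, ]))
  }, subsets)
  if (length(cliques) == 0) return(list())
  nc <- length(cliques)
  # clique adjacency graph, components by flood fill over clique ids
  adj <- lapply(seq_len(nc), function(i) {
    which(vapply(seq_len(nc), function(j) {
      i != j && length(intersect(cliques[[i]], cliques[[j]])) >= k - 1
    }, logical(1)))
  })
  unseen <- seq_len(nc)
  comms <- list()
  while (length(unseen) > 0) {
    frontier <- unseen[1]
    grp <- integer(0)
    while (length(frontier) > 0) {
      grp <- union(grp, frontier)
      frontier <- setdiff(unique(unlist(adj[frontier])), grp)
    }
    comms[[length(comms) + 1]] <- sort(unique(unlist(cliques[grp])))
    unseen <- setdiff(unseen, grp)
  }
  comms[order(vapply(comms, `[`, character(1), 1))]
}

# canonical form for comparing community sets
canonical_communities <- function(comms) {
  comms <- lapply(comms, sort)
  comms[order(vapply(comms, paste, character(1), collapse = ","))]
}
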