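#' Build an annotated interaction graph
#'
#' Constructs a simple (no self-loops, no multi-edges), undirected, unweighted
#' graph from a table of interaction records, attaching per-node functional
#' category sets. Duplicate records of the same unordered pair are collapsed;
#' the maximum confidence seen for a pair is kept as an edge attribute for
#' provenance only — all analyses treat the graph as unweighted. Nodes absent
#' from the annotation table carry an empty category set.
#'
#' @param interactions A tibble with columns `protein_a`, `protein_b` and
#'   optionally `confidence` (see [read_interactions()]). May be empty.
#' @param annotations Optional annotation table with columns `node`,
#'   `category` (see [read_annotations()]), covering any subset of nodes.
#' @return An `annotated_graph`: an igraph object with a list-valued vertex
#'   attribute `categories`, and class `annotated_graph` prepended.
#' @export
#' @examples
#' rec <- tibble::tibble(protein_a = c("a", "b"), protein_b = c("b", "c"),
#'                       confidence = c(0.9, 0.8))
#' ann <- tibble::tibble(node = c("a", "b"), category = "polarity")
#' g <- build_graph(rec, ann)
#' network_summary(g)
build_graph <- function(interactions, annotations = NULL) {
  if (is.null(interactions) || nrow(interactions) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(set_annotations(as_annotated(g), annotations))
  }
  conf <- if ("confidence" %in% names(interactions)) interactions$confidence else 1
  df <- tibble::tibble(
    from = pmin(interactions$protein_a, interactions$protein_b),
    to = pmax(interactions$protein_a, interactions$protein_b),
    confidence = conf
  )
  df <- df[df$from != df$to, ]
  df <- df |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop")
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  set_annotations(as_annotated(g), annotations)
}

as_annotated <- function(g) {
  if (!inherits(g, "annotated_graph")) class(g) <- c("annotated_graph", class(g))
  g
}

set_annotations <- function(g, annotations) {
  nodes <- igraph::V(g)$name %||% character(0)
  cats <- rep(list(character(0)), length(nodes))
  if (!is.null(annotations) && nrow(annotations) > 0 && length(nodes) > 0) {
    ann <- annotations[annotations$node %in% nodes, , drop = FALSE]
    by_node <- split(ann$category, ann$node)
    idx <- match(names(by_node), nodes)
    cats[idx] <- lapply(by_node, function(x) sort(unique(x)))
  }
  if (length(nodes) > 0) igraph::V(g)$categories <- cats
  g
}

#' @export
print.annotated_graph <- function(x, ...) {
  n <- igraph::vcount(x)
  m <- igraph::ecount(x)
  n_ann <- sum(lengths(node_categories(x)) > 0)
  cat(sprintf("<annotated_graph> %d nodes, %d edges, %d annotated node(s)\n",
              n, m, n_ann))
  cats <- category_universe(x)
  if (length(cats)) cat("categories:", paste(cats, collapse = ", "), "\n")
  invisible(x)
}

#' Node and edge tables of an annotated graph
#'
#' @param graph An `annotated_graph`.
#' @return `graph_nodes()`: a tibble with `node` and list-column `categories`.
#'   `graph_edges()`: a tibble with `from`, `to` (lexicographically ordered
#'   within a row) and `confidence`.
#' @export
graph_nodes <- function(graph) {
  tibble::tibble(
    node = igraph::V(graph)$name %||% character(0),
    categories = node_categories(graph)
  )
}

#' @rdname graph_nodes
#' @export
graph_edges <- function(graph) {
  if (igraph::ecount(graph) == 0) {
    return(tibble::tibble(from = character(0), to = character(0),
                          confidence = numeric(0)))
  }
  el <- igraph::as_edgelist(graph)
  conf <- igraph::E(graph)$confidence %||% rep(1, nrow(el))
  tibble::tibble(from = pmin(el[, 1], el[, 2]),
                 to = pmax(el[, 1], el[, 2]),
                 confidence = conf) |>
    dplyr::arrange(.data$from, .data$to)
}

# per-node category sets, as a list of character vectors in vertex order
node_categories <- function(graph) {
  if (igraph::vcount(graph) == 0) return(list())
  cats <- igraph::V(graph)$categories
  if (is.null(cats)) cats <- rep(list(character(0)), igraph::vcount(graph))
  lapply(cats, function(x) if (is.null(x)) character(0) else x)
}

#' Categories present in a graph's annotations
#'
#' @param graph An `annotated_graph`.
#' @return Sorted character vector of category labels.
#' @export
category_universe <- function(graph) {
  sort(unique(unlist(node_categories(graph))))
}

#' Extract the largest connected component
#'
#' Induced subgraph on the largest connected component. A size tie between
#' components is broken deterministically in favour of the component
#' containing the lexicographically smallest node identifier.
#'
#' @param graph An `annotated_graph`.
#' @return The induced `annotated_graph` (the empty graph stays empty).
#' @export
largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0) return(graph)
  comp <- igraph::components(graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(graph)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  keep <- which(comp$membership == best)
  as_annotated(igraph::induced_subgraph(graph, keep))
}

#' Induced sub-network of one functional category
#'
#' The induced subgraph on all nodes carrying the given category label.
#' Centrality analyses downstream take the largest component of this
#' subgraph (see [linkerity_table()]).
#'
#' @param graph An `annotated_graph`.
#' @param category A category label.
#' @return The induced `annotated_graph` (possibly empty).
#' @export
subnetwork <- function(graph, category) {
  cats <- node_categories(graph)
  keep <- which(vapply(cats, function(x) category %in% x, logical(1)))
  as_annotated(igraph::induced_subgraph(graph, keep))
}

#' Size and density summary of a graph's largest component
#'
#' Edge density is `2m / (n (n - 1))` over the largest connected component;
#' components with fewer than 2 nodes have density 0 by convention.
#'
#' @param graph An `annotated_graph`.
#' @return A one-row tibble: `n_nodes_total`, `n_nodes_largest_component`,
#'   `n_edges_largest_component`, `edge_density`.
#' @export
network_summary <- function(graph) {
  lc <- largest_component(graph)
  n <- igraph::vcount(lc)
  m <- igraph::ecount(lc)
  tibble::tibble(
    n_nodes_total = igraph::vcount(graph),
    n_nodes_largest_component = n,
    n_edges_largest_component = m,
    edge_density = if (n >= 2) 2 * m / (n * (n - 1)) else 0
  )
}

#' Interpolate the cutoff giving a target component size
#'
#' Given a curve of (confidence cutoff, largest-component size) pairs —
#' monotone non-increasing in size as the cutoff grows — estimates by linear
#' interpolation the cutoff at which the component would reach a target
#' size. Used to place score-free (BioGRID-style) networks on a STRING
#' cutoff axis. No extrapolation: a target outside the curve's size range is
#' an error.
#'
#' @param size_curve A data frame with columns `cutoff` and `size`.
#' @param target_size Target component size (count).
#' @return The interpolated cutoff (single numeric).
#' @export
#' @examples
#' curve <- tibble::tibble(cutoff = c(0.4, 0.7), size = c(1000, 600))
#' interpolate_equivalent_cutoff(curve, 800)
interpolate_equivalent_cutoff <- function(size_curve, target_size) {
  abort_if(!all(c("cutoff", "size") %in% names(size_curve)),
           "`size_curve` needs columns `cutoff` and `size`")
  sc <- dplyr::arrange(tibble::as_tibble(size_curve), .data$cutoff)
  abort_if(any(diff(sc$size) > 0),
           "`size_curve` must be non-increasing in size as cutoff grows")
  rng <- range(sc$size)
  abort_if(target_size < rng[1] || target_size > rng[2],
           sprintf("target size %g outside curve range [%g, %g]",
                   target_size, rng[1], rng[2]))
  sc <- dplyr::arrange(sc, .data$size)
  stats::approx(x = sc$size, y = sc$cutoff, xout = target_size,
                ties = "ordered")$y
}

#' Write / read the canonical edge-list dialect
#'
#' Tab-separated `node_a<TAB>node_b<TAB>confidence`, endpoints ordered
#' lexicographically within a row, rows sorted — so writes are deterministic
#' and a write/read round trip reproduces the node/edge set of the graph
#' (isolated nodes are not representable in an edge list).
#'
#' @param graph An `annotated_graph`.
#' @param file Output path.
#' @return `write_edgelist()`: the input graph, invisibly. `read_edgelist()`:
#'   a tibble of interaction records suitable for [build_graph()].
#' @export
write_edgelist <- function(graph, file) {
  readr::write_tsv(graph_edges(graph), file, col_names = FALSE,
                   progress = FALSE)
  invisible(graph)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(file) {
  read_interactions(file, columns = c(a = 1, b = 2, confidence = 3))
}
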