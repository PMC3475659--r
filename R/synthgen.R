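# Synthetic annotated networks with planted structure.
#
# These generators are the package's no-download test surface: they emulate
# the modular, overlapping-annotation structure of a functional core network
# (dense within-category wiring, sparse between-category wiring, planted
# linker nodes that are peripheral in their own module but bridge into
# another) without attempting to match any real organism's statistics.

#' Generate a modular annotated network with planted linkers
#'
#' Builds `n_modules` Erdős–Rényi blocks of `module_size` nodes wired
#' internally with probability `p_in` and across modules with probability
#' `p_out` (`p_in > p_out` gives planted functional modularity). Each
#' module's nodes carry that module's category label. For every unordered
#' module pair, `n_linkers_per_pair` extra linker nodes are planted,
#' alternating their home module within the pair: a linker carries exactly
#' its home module's category but attaches with `linker_edges_within` edges
#' inside its home module and `linker_edges_between` edges into the other
#' module of the pair — peripheral locally, central globally, the structure
#' a high linkerity score is designed to detect.
#'
#' Optionally, a fraction of regular nodes receives a second category
#' (`overlap_fraction`) and a fixed number receives every category
#' (`n_full_overlap`), mimicking multifunctional proteins. Essentiality
#' labels are planted on `essential_fraction` of the nodes with sampling
#' weight proportional to degree rank, so hubs are enriched for essential
#' genes as in real interaction networks.
#'
#' @param n_modules Number of modules/categories (default 3).
#' @param module_size Regular nodes per module (default 40).
#' @param p_in Within-module edge probability (default 0.3).
#' @param p_out Between-module edge probability (default 0.01).
#' @param n_linkers_per_pair Planted linkers per module pair (default 2).
#' @param linker_edges_within Linker edges into its home module (default 4,
#'   well below the expected within-module degree of 12, so the linker stays
#'   peripheral in its own sub-network).
#' @param linker_edges_between Linker edges into the paired module (default
#'   20: the linker must concentrate enough cross-module attachment to carry
#'   inter-module shortest paths against the background of random `p_out`
#'   cross edges, otherwise it is not a bridge).
#' @param overlap_fraction Fraction of regular nodes given one extra
#'   category (default 0).
#' @param n_full_overlap Number of regular nodes given all categories
#'   (default 0).
#' @param essential_fraction Fraction of nodes labelled essential
#'   (default 0.3).
#' @param categories Category labels, one per module (default
#'   `"cat1"..."catN"`).
#' @param seed Optional integer seed; the generator is a pure function of
#'   its arguments and the seed.
#' @return A list with `graph` (an `annotated_graph`), `truth` (list:
#'   `planted_linkers`, `planted_essential`, `module_assignment` tibble
#'   with `node`, `module`, `category`), and `lethality` (tibble `node`,
#'   `lethality` with `"E"`/`"V"` labels).
#' @export
#' @examples
#' net <- generate_modular_network(seed = 7)
#' net$graph
#' head(net$truth$planted_linkers)
generate_modular_network <- function(n_modules = 3, module_size = 40,
                                     p_in = 0.3, p_out = 0.01,
                                     n_linkers_per_pair = 2,
                                     linker_edges_within = 4,
                                     linker_edges_between = 20,
                                     overlap_fraction = 0,
                                     n_full_overlap = 0,
                                     essential_fraction = 0.3,
                                     categories = NULL, seed = NULL) {
  abort_if(p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1,
           "`p_in` and `p_out` must be in [0,1]")
  abort_if(!is.null(categories) && length(categories) != n_modules,
           "need one category label per module")
  categories <- categories %||% paste0("cat", seq_len(n_modules))
  if ((module_size - 1) * p_in < 1) {
    rlang::warn("expected within-module degree below 1; modules may shatter")
  }
  with_seed_opt(seed, {
    module_nodes <- lapply(seq_len(n_modules), function(mod) {
      sprintf("m%d_%02d", mod, seq_len(module_size))
    })
    edges_from <- character(0)
    edges_to <- character(0)
    add_pairs <- function(nodes_i, nodes_j, p) {
      # nodes_i == nodes_j: within-block pairs; else all cross pairs
      if (identical(nodes_i, nodes_j)) {
        npairs <- length(nodes_i) * (length(nodes_i) - 1) / 2
        pick <- which(stats::runif(npairs) < p)
        if (length(pick)) {
          ij <- decode_pair(pick, length(nodes_i))
          list(from = nodes_i[ij[, 1]], to = nodes_i[ij[, 2]])
        } else list(from = character(0), to = character(0))
      } else {
        grid <- expand.grid(a = nodes_i, b = nodes_j,
                            stringsAsFactors = FALSE)
        pick <- stats::runif(nrow(grid)) < p
        list(from = grid$a[pick], to = grid$b[pick])
      }
    }
    for (mod in seq_len(n_modules)) {
      e <- add_pairs(module_nodes[[mod]], module_nodes[[mod]], p_in)
      edges_from <- c(edges_from, e$from)
      edges_to <- c(edges_to, e$to)
    }
    pairs <- if (n_modules > 1) utils::combn(n_modules, 2) else
      matrix(integer(0), nrow = 2)
    for (pp in seq_len(ncol(pairs))) {
      e <- add_pairs(module_nodes[[pairs[1, pp]]],
                     module_nodes[[pairs[2, pp]]], p_out)
      edges_from <- c(edges_from, e$from)
      edges_to <- c(edges_to, e$to)
    }
    # planted linkers: home module alternates within each pair
    linkers <- character(0)
    linker_module <- integer(0)
    for (pp in seq_len(ncol(pairs))) {
      a <- pairs[1, pp]; b <- pairs[2, pp]
      for (l in seq_len(n_linkers_per_pair)) {
        home <- if (l %% 2 == 1) a else b
        away <- if (home == a) b else a
        name <- sprintf("linker%d_%d_%d", a, b, l)
        linkers <- c(linkers, name)
        linker_module <- c(linker_module, home)
        nbr_in <- sample(module_nodes[[home]],
                         min(linker_edges_within, module_size))
        nbr_out <- sample(module_nodes[[away]],
                          min(linker_edges_between, module_size))
        edges_from <- c(edges_from, rep(name, length(nbr_in) + length(nbr_out)))
        edges_to <- c(edges_to, nbr_in, nbr_out)
      }
    }
    regular <- unlist(module_nodes)
    ann <- tibble::tibble(
      node = c(regular, linkers),
      category = categories[c(rep(seq_len(n_modules), each = module_size),
                              linker_module)]
    )
    if (overlap_fraction > 0 && n_modules > 1) {
      n_extra <- round(overlap_fraction * length(regular))
      extra_nodes <- sample(regular, n_extra)
      own <- match(ann$category[match(extra_nodes, ann$node)], categories)
      second <- vapply(own, function(o) {
        sample(setdiff(seq_len(n_modules), o), 1)
      }, integer(1))
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        node = extra_nodes, category = categories[second]))
    }
    if (n_full_overlap > 0) {
      multi <- sample(setdiff(regular, ann$node[duplicated(ann$node)]),
                      n_full_overlap)
      ann <- dplyr::bind_rows(
        ann, tidyr::expand_grid(node = multi, category = categories))
    }
    rec <- tibble::tibble(protein_a = edges_from, protein_b = edges_to,
                          confidence = 1)
    graph <- build_graph(rec, as_annotations(ann))
    deg <- igraph::degree(graph)
    n_ess <- round(essential_fraction * length(deg))
    essential <- sample(names(deg), n_ess,
                        prob = rank(deg, ties.method = "average"))
    lethality <- tibble::tibble(
      node = names(deg),
      lethality = ifelse(names(deg) %in% essential, "E", "V"))
    truth <- list(
      planted_linkers = linkers,
      planted_essential = sort(essential),
      module_assignment = tibble::tibble(
        node = c(regular, linkers),
        module = c(rep(seq_len(n_modules), each = module_size),
                   linker_module),
        category = categories[c(rep(seq_len(n_modules), each = module_size),
                                linker_module)])
    )
    list(graph = graph, truth = truth, lethality = lethality)
  })
}

#' Generate a scale-free network by preferential attachment
#'
#' Barabási–Albert growth: nodes are added one at a time, each attaching
#' `attach` edges to existing nodes with probability proportional to their
#' degree. Produces the heavy-tailed degree distribution used to exercise
#' the power-law fit.
#'
#' @param n Number of nodes.
#' @param attach Edges added per new node (`1 <= attach < n`).
#' @param seed Optional integer seed.
#' @return An `annotated_graph` (no annotations) with nodes `v1...vn`.
#' @export
generate_scale_free <- function(n, attach = 2, seed = NULL) {
  abort_if(attach < 1 || attach >= n, "need `n > attach >= 1`")
  g <- with_seed_opt(seed, igraph::sample_pa(n, m = attach, directed = FALSE))
  g <- igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n)))
  g <- igraph::simplify(g)
  g <- igraph::set_vertex_attr(g, "categories",
                               value = rep(list(character(0)), n))
  as_annotated(g)
}

#' Fixed two-category toy network with one planted linker
#'
#' An 11-node, 16-edge graph with two functional categories: a 6-node
#' module `A1..A5 + L` (category `"alpha"`) and a 5-node module `B1..B5`
#' (category `"beta"`). The planted linker `L` hangs off the periphery of
#' its own module by a single edge but carries three edges into module B —
#' it is the sole bridge, so every cross-module shortest path runs through
#' it. Within its own sub-network `L` has betweenness 0 (worst average-tie
#' rank, 5.5, shared with `A1`), while in the full graph it has the highest
#' betweenness among category-alpha members (rank 1), giving it the maximum
#' linkerity 5.5. The module hub `A4` moves the other way (rank 1 locally,
#' rank 3 in the core; linkerity 1/3).
#'
#' The expected table was computed once with an independent shortest-path
#' oracle and is frozen here; it is the reference truth for pipeline tests.
#'
#' @return A list with `graph` (the `annotated_graph`) and `expected` (a
#'   tibble with the category-alpha linkerity records: `node`,
#'   `categories`, `rank_sub`, `rank_core`, `linkerity`).
#' @export
toy_linker_fixture <- function() {
  rec <- tibble::tibble(
    protein_a = c("A1", "A1", "A2", "A2", "A3", "A4",
                  "B1", "B1", "B2", "B3", "B2", "B4",
                  "L", "L", "L", "L"),
    protein_b = c("A2", "A3", "A3", "A4", "A4", "A5",
                  "B2", "B3", "B3", "B4", "B5", "B5",
                  "A5", "B1", "B2", "B3"),
    confidence = 1
  )
  ann <- tibble::tibble(
    node = c("A1", "A2", "A3", "A4", "A5", "L",
             "B1", "B2", "B3", "B4", "B5"),
    category = rep(c("alpha", "beta"), c(6, 5))
  )
  expected <- tibble::tibble(
    node = c("L", "A5", "A1", "A2", "A3", "A4"),
    categories = "alpha",
    rank_sub = c(5.5, 2, 5.5, 3.5, 3.5, 1),
    rank_core = c(1, 2, 6, 4.5, 4.5, 3),
    linkerity = c(5.5, 1, 5.5 / 6, 3.5 / 4.5, 3.5 / 4.5, 1 / 3)
  )
  list(graph = build_graph(rec, ann), expected = expected)
}
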