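# fixture builders shared across test files (everything generated in code)

# quick graph from a vector of "a-b" edge strings, optional annotations
tiny_graph <- function(edge_spec, annotations = NULL) {
  parts <- strsplit(edge_spec, "-", fixed = TRUE)
  rec <- tibble::tibble(
    protein_a = vapply(parts, `[`, character(1), 1),
    protein_b = vapply(parts, `[`, character(1), 2),
    confidence = 1
  )
  ann <- if (!is.null(annotations)) {
    tibble::tibble(node = names(annotations),
                   category = unname(annotations)) |>
      tidyr::separate_longer_delim("category", ",")
  }
  build_graph(rec, ann)
}

# connected Erdos-Renyi-ish random graph for oracle comparisons: resample
# until connected (n small, p generous)
random_connected_graph <- function(n, p = 0.35) {
  nodes <- sprintf("n%02d", seq_len(n))
  repeat {
    prs <- utils::combn(nodes, 2)
    keep <- stats::runif(ncol(prs)) < p
    if (!any(keep)) next
    rec <- tibble::tibble(protein_a = prs[1, keep], protein_b = prs[2, keep],
                          confidence = 1)
    g <- build_graph(rec)
    if (igraph::vcount(g) == n &&
        igraph::count_components(g) == 1) return(g)
  }
}

# random (not necessarily connected) graph over exactly n named nodes
random_graph_fixed_nodes <- function(n, p = 0.25) {
  nodes <- sprintf("n%02d", seq_len(n))
  prs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(prs)) < p
  rec <- tibble::tibble(protein_a = prs[1, keep], protein_b = prs[2, keep],
                        confidence = 1)
  g <- build_graph(rec)
  # add isolated nodes so the vertex set is always the full n
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing)) {
    g <- igraph::add_vertices(g, length(missing), name = missing,
                              attr = list(categories = rep(list(character(0)),
                                                           length(missing))))
  }
  linkerity:::as_annotated(g)
}

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
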