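#' Read functional category annotations
#'
#' Reads a two-column TSV mapping node identifiers to functional category
#' labels and applies umbrella merges: when several specific labels describe
#' one biological function (in fission yeast, "establishment or maintenance
#' of cell polarity" and "cell morphogenesis" both describe polarity), each
#' child label is replaced by its umbrella label before storage, so a node
#' annotated to any child carries the umbrella category.
#'
#' @param file Path to a TSV with columns `node`, `category` (no header), or
#'   a character vector of lines.
#' @param umbrella Optional named character vector mapping child label ->
#'   umbrella label (or a single-level named list, as read from YAML).
#' @return A tibble with columns `node`, `category`, one row per
#'   (node, category) pair, deduplicated and sorted.
#' @export
#' @examples
#' lines <- c("for3\testablishment-of-polarity", "for3\tcell-morphogenesis")
#' read_annotations(lines, umbrella = c(
#'   "establishment-of-polarity" = "polarity",
#'   "cell-morphogenesis" = "polarity"))
read_annotations <- function(file, umbrella = NULL) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    lines <- readr::read_lines(file)
  } else {
    lines <- unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(node = character(0), category = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2
  if (any(!ok)) rlang::inform(sprintf("skipped %d malformed annotation line(s)",
                                      sum(!ok)))
  ann <- tibble::tibble(
    node = vapply(fields[ok], function(f) trimws(f[[1]]), character(1)),
    category = vapply(fields[ok], function(f) trimws(f[[2]]), character(1))
  )
  apply_umbrella(ann, umbrella)
}

#' Coerce a data frame to the annotation-table shape
#'
#' @param df A data frame with columns `node` and `category`.
#' @inheritParams read_annotations
#' @return A tibble with columns `node`, `category`, umbrella-merged and
#'   deduplicated.
#' @export
as_annotations <- function(df, umbrella = NULL) {
  abort_if(!all(c("node", "category") %in% names(df)),
           "annotation table needs columns `node` and `category`")
  apply_umbrella(tibble::as_tibble(df)[c("node", "category")], umbrella)
}

apply_umbrella <- function(ann, umbrella) {
  if (!is.null(umbrella)) {
    umbrella <- unlist(umbrella)
    hit <- ann$category %in% names(umbrella)
    ann$category[hit] <- unname(umbrella[ann$category[hit]])
  }
  dplyr::distinct(dplyr::arrange(ann, .data$node, .data$category))
}

#' Exact-subset (Venn) partition of annotated nodes
#'
#' Counts, for every non-empty subset of the category universe, the nodes
#' annotated with exactly that subset — the counts behind a Venn diagram of
#' functional groups. Counts over all occupied subsets sum to the number of
#' annotated nodes.
#'
#' @param annotations An annotation table (`node`, `category`), or an
#'   `annotated_graph` whose node annotations are used.
#' @param drop_empty If `TRUE` (default) omit unoccupied subsets.
#' @return A tibble with `categories` (subset label, members joined by
#'   `"+"` in universe order), `n_categories`, and `n` (node count), sorted
#'   by subset size then label.
#' @export
venn_partition <- function(annotations, drop_empty = TRUE) {
  ann <- if (inherits(annotations, "annotated_graph")) {
    nodes <- graph_nodes(annotations)
    tidyr::unnest(nodes[lengths(nodes$categories) > 0, ], "categories") |>
      dplyr::rename(category = "categories")
  } else {
    tibble::as_tibble(annotations)
  }
  universe <- sort(unique(ann$category))
  abort_if(length(universe) == 0, "no categories to partition")
  subset_of <- ann |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(
      categories = paste(universe[universe %in% .data$category], collapse = "+"),
      n_categories = dplyr::n_distinct(.data$category),
      .groups = "drop")
  counts <- subset_of |>
    dplyr::count(.data$categories, .data$n_categories, name = "n")
  if (!drop_empty) {
    all_subsets <- unlist(lapply(seq_along(universe), function(k) {
      apply(utils::combn(universe, k), 2, paste, collapse = "+")
    }))
    counts <- tibble::tibble(
      categories = all_subsets,
      n_categories = rep(seq_along(universe),
                         times = choose(length(universe), seq_along(universe)))
    ) |>
      dplyr::left_join(counts[c("categories", "n")], by = "categories") |>
      dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  }
  dplyr::arrange(counts, .data$n_categories, .data$categories)
}

#' Classify edges by annotation sharing
#'
#' Labels each edge `shared` when the endpoint category sets intersect,
#' `unshared` when both endpoints are annotated but the sets are disjoint,
#' and `unannotated` when either endpoint has no category. This is the edge
#' colouring of the core-network figure (grey = shared, black = unshared).
#'
#' @param graph An `annotated_graph`.
#' @param exclude Optional character vector of node identifiers to treat as
#'   unannotated — an exclusion list for proteins annotated only through a
#'   child term common to two categories (the GO tree itself is not
#'   consulted).
#' @return A tibble with `from`, `to`, `status` (one row per edge), with a
#'   summary attribute `counts` (named integer vector of the three statuses).
#' @export
classify_edges <- function(graph, exclude = NULL) {
  edges <- graph_edges(graph)
  cats <- node_categories(graph)
  names(cats) <- igraph::V(graph)$name
  if (!is.null(exclude)) cats[names(cats) %in% exclude] <- list(character(0))
  status <- vapply(seq_len(nrow(edges)), function(i) {
    ca <- cats[[edges$from[i]]]
    cb <- cats[[edges$to[i]]]
    if (length(ca) == 0 || length(cb) == 0) return("unannotated")
    if (length(intersect(ca, cb)) > 0) "shared" else "unshared"
  }, character(1))
  out <- tibble::tibble(from = edges$from, to = edges$to, status = status)
  attr(out, "counts") <- c(
    shared = sum(status == "shared"),
    unshared = sum(status == "unshared"),
    unannotated = sum(status == "unannotated")
  )
  out
}
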