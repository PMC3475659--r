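#' Read a tab-separated protein interaction table
#'
#' Parses STRING- or BioGRID-style interaction snapshots (a PSI-MI-TAB-like
#' dialect) into a tidy table of scored undirected interactions. Column
#' positions are configurable because snapshot layouts differ between
#' databases and versions. STRING exports carry a combined confidence score
#' in \[0,1\]; BioGRID exports have no score, in which case every record gets
#' confidence 1 and evidence `"physical"`.
#'
#' Identifiers are normalised through an optional alias map (alias ->
#' canonical), since interaction databases and annotation sources sometimes
#' name the same gene differently. Self-interactions (after alias resolution)
#' are dropped and counted. Malformed lines (too few columns, unparsable or
#' out-of-range score) are skipped and counted; more than 50% malformed lines
#' is an error.
#'
#' @param file Path to a tab-separated file (UTF-8), or a character vector of
#'   lines.
#' @param columns Named integer vector giving 1-based column indices, with
#'   required names `a` and `b` and optional `confidence` and `evidence`.
#'   Default `c(a = 1, b = 2, confidence = 3, evidence = 4)`.
#' @param aliases Optional alias map: a data frame with columns `alias` and
#'   `canonical`, or a named character vector (names = aliases).
#' @param physical_only If `TRUE`, keep only records whose evidence tag is
#'   `"physical"` (for BioGRID-style inputs mixing physical and genetic
#'   interactions).
#' @param skip Number of header lines to skip (default 0; lines starting with
#'   `#` are always skipped).
#' @return A tibble with columns `protein_a`, `protein_b`, `confidence`,
#'   `evidence`, one row per retained interaction record. Counts of dropped
#'   lines are attached as attributes `n_malformed`, `n_self`,
#'   `n_unresolved_alias`.
#' @seealso [filter_by_confidence()], [build_graph()]
#' @export
#' @examples
#' lines <- c("cdc2\twee1\t0.95\tphysical", "cdc2\tcdc13\t0.9\tphysical")
#' read_interactions(lines)
read_interactions <- function(file,
                              columns = c(a = 1, b = 2, confidence = 3, evidence = 4),
                              aliases = NULL,
                              physical_only = FALSE,
                              skip = 0) {
  abort_if(!all(c("a", "b") %in% names(columns)),
           "`columns` must name at least `a` and `b` indices")
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    lines <- readr::read_lines(file)
  } else {
    lines <- unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }
  if (skip > 0) lines <- lines[-seq_len(min(skip, length(lines)))]
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  abort_if(length(lines) == 0, "no interaction records in input")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(columns[c("a", "b")])
  has_conf <- "confidence" %in% names(columns)
  has_evid <- "evidence" %in% names(columns)

  parse_one <- function(f) {
    if (length(f) < need) return(NULL)
    a <- trimws(f[[columns[["a"]]]])
    b <- trimws(f[[columns[["b"]]]])
    if (!nzchar(a) || !nzchar(b)) return(NULL)
    conf <- 1.0
    evid <- "physical"
    if (has_conf && length(f) >= columns[["confidence"]]) {
      raw <- trimws(f[[columns[["confidence"]]]])
      if (nzchar(raw)) {
        conf <- suppressWarnings(as.numeric(raw))
        if (is.na(conf) || conf < 0 || conf > 1) return(NULL)
      }
    }
    if (has_evid && length(f) >= columns[["evidence"]]) {
      raw <- trimws(f[[columns[["evidence"]]]])
      if (nzchar(raw)) evid <- raw
    }
    list(a = a, b = b, confidence = conf, evidence = evid)
  }

  parsed <- lapply(fields, parse_one)
  ok <- !vapply(parsed, is.null, logical(1))
  n_malformed <- sum(!ok)
  if (n_malformed > length(lines) / 2) {
    rlang::abort(sprintf(
      "%d of %d lines malformed (>50%%); check `columns` mapping",
      n_malformed, length(lines)))
  }
  parsed <- parsed[ok]
  rec <- tibble::tibble(
    protein_a = vapply(parsed, `[[`, character(1), "a"),
    protein_b = vapply(parsed, `[[`, character(1), "b"),
    confidence = vapply(parsed, `[[`, numeric(1), "confidence"),
    evidence = normalise_evidence(vapply(parsed, `[[`, character(1), "evidence"))
  )

  n_unresolved <- 0L
  if (!is.null(aliases)) {
    map <- as_alias_map(aliases)
    rec$protein_a <- resolve_alias(rec$protein_a, map)
    rec$protein_b <- resolve_alias(rec$protein_b, map)
  }
  self <- rec$protein_a == rec$protein_b
  n_self <- sum(self)
  if (n_self > 0) {
    rlang::inform(sprintf("dropped %d self-interaction(s)", n_self))
    rec <- rec[!self, ]
  }
  if (physical_only) rec <- rec[rec$evidence == "physical", ]
  if (n_malformed > 0) {
    rlang::inform(sprintf("skipped %d malformed line(s)", n_malformed))
  }
  attr(rec, "n_malformed") <- n_malformed
  attr(rec, "n_self") <- n_self
  attr(rec, "n_unresolved_alias") <- n_unresolved
  rec
}

normalise_evidence <- function(x) {
  known <- c("physical", "genetic", "inferred")
  ifelse(tolower(x) %in% known, tolower(x), "unknown")
}

as_alias_map <- function(aliases) {
  if (is.data.frame(aliases)) {
    stats::setNames(as.character(aliases$canonical), as.character(aliases$alias))
  } else {
    abort_if(is.null(names(aliases)), "alias map must be named or a data frame")
    aliases
  }
}

resolve_alias <- function(x, map) {
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}

#' Keep interactions at or above a confidence cutoff
#'
#' Mirrors the confidence-cutoff step used to reject weakly supported
#' STRING interactions before graph construction. The comparison is
#' `confidence >= cutoff`, so the boundary score is retained.
#'
#' @param interactions A tibble as returned by [read_interactions()].
#' @param cutoff Confidence cutoff in \[0,1\].
#' @return The filtered tibble. Warns if nothing survives.
#' @export
filter_by_confidence <- function(interactions, cutoff) {
  abort_if(!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff > 1,
           "`cutoff` must be a single number in [0,1]")
  out <- dplyr::filter(interactions, .data$confidence >= cutoff)
  if (nrow(out) == 0 && nrow(interactions) > 0) {
    rlang::warn(sprintf("no interactions at confidence >= %g", cutoff))
  }
  out
}

#' Read a two-column alias map from TSV
#'
#' @param file Path to a TSV with columns `alias`, `canonical` (no header).
#' @return A tibble with columns `alias` and `canonical`.
#' @export
read_aliases <- function(file) {
  readr::read_tsv(file, col_names = c("alias", "canonical"),
                  col_types = "cc", progress = FALSE)
}
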