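#' Run the full linker-detection pipeline
#'
#' Executes the standard workflow on local snapshot files: parse the
#' interaction table, apply the confidence cutoff, build the annotated
#' graph, take the largest component, rank nodes, compute linkerity tables
#' per category, and optionally run the modularity null model, the
#' perturbation robustness protocol, k-clique communities and neighbour
#' heterogeneity. Writes deterministic TSV/JSON artifacts plus a
#' machine-readable manifest (inputs, counts, seed) to the output
#' directory; re-running the same config and seed reproduces byte-identical
#' tables.
#'
#' @param config A named list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{`interactions`}{path to the interaction TSV (required).}
#'     \item{`annotations`}{path to the annotation TSV (required).}
#'     \item{`cutoff`}{confidence cutoff in \[0,1\] (default 0.7).}
#'     \item{`columns`}{named column indices for the interaction dialect.}
#'     \item{`aliases`}{optional path to an alias TSV.}
#'     \item{`physical_only`}{keep only physical-evidence records.}
#'     \item{`umbrella`}{named child -> umbrella category map.}
#'     \item{`categories`}{categories to analyse (default: all).}
#'     \item{`seed`}{integer seed for stochastic stages.}
#'     \item{`stages`}{subset of `"nullmodel"`, `"perturb"`,
#'       `"communities"`, `"heterogeneity"` to run beyond the core stages.}
#'     \item{`n_replicates`}{replicates for nullmodel/perturb stages
#'       (default 1000).}
#'     \item{`perturbation`}{list with `model` and `fraction` (default
#'       `add_random`, 0.1).}
#'     \item{`k`}{clique size for communities (default 4).}
#'   }
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the built objects (`core`, `summary`,
#'   `linkerity`, and any optional stage results) and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cutoff <- config$cutoff %||% 0.7
  abort_if(!is.numeric(cutoff) || cutoff < 0 || cutoff > 1,
           "config: `cutoff` must be in [0,1]")
  abort_if(is.null(config$interactions) || !file.exists(config$interactions),
           "config: `interactions` file missing")
  abort_if(is.null(config$annotations) || !file.exists(config$annotations),
           "config: `annotations` file missing")
  stages <- config$stages %||% character(0)
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_out <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }
  write_json_out <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  columns <- unlist(config$columns %||%
                      c(a = 1, b = 2, confidence = 3, evidence = 4))
  aliases <- if (!is.null(config$aliases)) read_aliases(config$aliases)
  rec <- stage("build", read_interactions(
    config$interactions, columns = columns, aliases = aliases,
    physical_only = isTRUE(config$physical_only)))
  rec <- filter_by_confidence(rec, cutoff)
  ann <- stage("annotate",
               read_annotations(config$annotations,
                                umbrella = config$umbrella))
  core <- largest_component(build_graph(rec, ann))
  summ <- network_summary(core)
  write_edgelist(core, file.path(out_dir, "core_edges.tsv"))
  write_json_out(as.list(summ), "network_summary.json")
  write_json_out(venn_partition(core), "venn.json")

  rank_bc <- stage("rank", average_rank(betweenness_scores(core)))
  rank_deg <- average_rank(degree_scores(core))
  write_tsv_out(rank_bc, "rank_betweenness.tsv")
  write_tsv_out(rank_deg, "rank_degree.tsv")

  categories <- config$categories %||% category_universe(core)
  lt <- stage("linkerity", linkerity_all(core, categories))
  write_tsv_out(lt, "linkerity.tsv")

  results <- list(core = core, summary = summ, linkerity = lt,
                  rank_betweenness = rank_bc, rank_degree = rank_deg)
  n_reps <- config$n_replicates %||% 1000

  if ("nullmodel" %in% stages) {
    nd <- stage("nullmodel", null_distribution(
      core, n_replicates = n_reps, seed = seed))
    write_json_out(glance(nd), "modularity_null.json")
    results$nullmodel <- nd
  }
  if ("perturb" %in% stages) {
    pspec <- config$perturbation %||% list()
    rs <- stage("perturb", robustness_summary(
      core, category = categories[[1]],
      model = pspec$model %||% "add_random",
      fraction = pspec$fraction %||% 0.1,
      n_replicates = n_reps, seed = seed))
    write_tsv_out(tibble::as_tibble(rs), "robustness.tsv")
    results$perturb <- rs
  }
  if ("communities" %in% stages) {
    cs <- stage("communities", k_clique_communities(core,
                                                    k = config$k %||% 4))
    write_tsv_out(tidy(cs), "communities.tsv")
    write_json_out(list(
      k = cs$k,
      communities = lapply(cs$communities, identity),
      composition = community_composition(cs, core)), "communities.json")
    results$communities <- cs
  }
  if ("heterogeneity" %in% stages) {
    het <- stage("heterogeneity", purrr::map_dfr(categories, function(cat) {
      prof <- neighbor_profiles(core, cat)
      assoc <- linkerity_heterogeneity_association(
        lt[lt$category == cat, ], prof)
      dplyr::mutate(assoc, category = cat, .before = 1)
    }))
    write_tsv_out(het, "heterogeneity.tsv")
    results$heterogeneity <- het
  }

  manifest <- list(
    package = "linkerity",
    version = as.character(utils::packageVersion("linkerity")),
    inputs = list(interactions = config$interactions,
                  annotations = config$annotations,
                  cutoff = cutoff,
                  physical_only = isTRUE(config$physical_only)),
    seed = seed,
    stages = c("build", "annotate", "rank", "linkerity", stages),
    counts = list(
      records_after_cutoff = nrow(rec),
      n_nodes_total = summ$n_nodes_total,
      n_nodes_largest_component = summ$n_nodes_largest_component,
      n_edges_largest_component = summ$n_edges_largest_component,
      n_malformed = attr(rec, "n_malformed") %||% 0,
      n_self = attr(rec, "n_self") %||% 0
    )
  )
  write_json_out(manifest, "manifest.json")
  results$manifest <- manifest
  invisible(results)
}
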