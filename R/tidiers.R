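#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return `tidy()`: the fitted histogram with observed and fitted log
#'   frequencies. `glance()`: a one-row tibble with `c`, `gamma`,
#'   `r_squared`, `n_bins`.
#' @export
tidy.power_law_fit <- function(x, ...) {
  dplyr::mutate(x$histogram,
                fitted = x$c * .data$degree^(-x$gamma))
}

#' @rdname tidy.power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(c = x$c, gamma = x$gamma, r_squared = x$r_squared,
                 n_bins = x$n_bins)
}

#' Tidy a modularity null distribution
#'
#' @param x A `modularity_null`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of null replicate ratios. `glance()`: a
#'   one-row tibble with the observed ratio, null mean, empirical p-value
#'   and replicate counts.
#' @export
tidy.modularity_null <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_ratios),
                 null_ratio = x$null_ratios)
}

#' @rdname tidy.modularity_null
#' @export
glance.modularity_null <- function(x, ...) {
  tibble::tibble(observed_ratio = x$observed_ratio,
                 null_mean = x$null_mean,
                 empirical_p = x$empirical_p,
                 n_replicates = x$n_replicates,
                 n_dropped = x$n_dropped,
                 model = x$model)
}

#' Tidy a community set
#'
#' @param x A `community_set`.
#' @param ... Unused.
#' @return `tidy()`: the long membership table (see
#'   [community_membership()]). `glance()`: one row with `k`,
#'   `n_communities`, `n_nodes` (distinct) and `n_memberships`.
#' @export
tidy.community_set <- function(x, ...) {
  community_membership(x)
}

#' @rdname tidy.community_set
#' @export
glance.community_set <- function(x, ...) {
  mem <- community_membership(x)
  tibble::tibble(k = x$k,
                 n_communities = length(x$communities),
                 n_nodes = dplyr::n_distinct(mem$node),
                 n_memberships = nrow(mem))
}

#' Summarise a perturbation robustness run
#'
#' @param x A `perturbation_summary`.
#' @param ... Unused.
#' @return One row with the perturbation model, fraction, replicate counts
#'   and the fraction of unperturbed top-decile nodes retained in the top
#'   quintile in at least 90% of replicates.
#' @export
glance.perturbation_summary <- function(x, ...) {
  n <- nrow(x)
  top10 <- x$node[order(x$rank_unperturbed, x$node)][seq_len(ceiling(0.1 * n))]
  retained <- x$freq_top20[match(top10, x$node)] >= 0.9
  tibble::tibble(
    model = attr(x, "model"),
    fraction = attr(x, "fraction"),
    rank_by = attr(x, "rank_by"),
    category = attr(x, "category"),
    n_replicates = attr(x, "n_replicates"),
    n_skipped = attr(x, "n_skipped"),
    n_nodes = n,
    top_decile_retained = mean(retained)
  )
}
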