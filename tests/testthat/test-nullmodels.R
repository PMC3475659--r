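test_that("fully random rewiring preserves node set, annotations, edge count", {
  # complete graph is forced back to itself
  k4 <- tiny_graph(c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D"))
  r4 <- rewire_random(k4, seed = 1)
  expect_equal(graph_edges(r4)[c("from", "to")], graph_edges(k4)[c("from", "to")])
  # arbitrary graphs keep m and the annotation map
  net <- generate_modular_network(module_size = 10, seed = 2)
  g <- net$graph
  rw <- rewire_random(g, seed = 3)
  expect_equal(igraph::ecount(rw), igraph::ecount(g))
  expect_setequal(igraph::V(rw)$name, igraph::V(g)$name)
  expect_equal(graph_nodes(rw)$categories[order(graph_nodes(rw)$node)],
               graph_nodes(g)$categories[order(graph_nodes(g)$node)])
  # simple graph: no loops or duplicates
  expect_false(igraph::any_loop(rw))
  expect_false(igraph::any_multiple(rw))
})

test_that("random rewiring drives same-annotation edges to the pair expectation", {
  # 20-node graph, 2 categories of 10; under uniform rewiring the expected
  # fraction of same-annotation edges is P_same / P_total
  ann <- c(stats::setNames(rep("c1", 10), sprintf("a%02d", 1:10)),
           stats::setNames(rep("c2", 10), sprintf("b%02d", 1:10)))
  g <- tiny_graph(c(paste0("a0", 1:9, "-a", sprintf("%02d", 2:10)),
                    paste0("b0", 1:9, "-b", sprintf("%02d", 2:10))),
                  annotations = ann)
  m <- igraph::ecount(g)
  p_same <- 2 * choose(10, 2) / choose(20, 2)
  fractions <- vapply(1:400, function(s) {
    counts <- attr(classify_edges(rewire_random(g, seed = s)), "counts")
    counts[["shared"]] / m
  }, numeric(1))
  se <- stats::sd(fractions) / sqrt(length(fractions))
  expect_lt(abs(mean(fractions) - p_same), 3 * se + 1e-12)
})

test_that("degree-preserving rewiring fixes the degree sequence bit-exactly", {
  k3 <- tiny_graph(c("A-B", "B-C", "A-C"))
  expect_equal(graph_edges(rewire_degree_preserving(k3, seed = 4)),
               graph_edges(k3))
  set.seed(77)
  for (i in 1:10) {
    g <- random_graph_fixed_nodes(sample(8:16, 1), p = 0.3)
    rw <- rewire_degree_preserving(g, n_swaps = 1000, seed = i)
    expect_identical(sort(as.integer(igraph::degree(rw))),
                     sort(as.integer(igraph::degree(g))))
    expect_false(igraph::any_loop(rw))
    expect_false(igraph::any_multiple(rw))
  }
  expect_warning(rewire_degree_preserving(tiny_graph("A-B")), "fewer than 2")
})

test_that("4-cycle swaps reach both members of its configuration class", {
  # degree sequence (2,2,2,2) admits exactly two simple graphs on 4 labelled
  # nodes containing a perfect matching structure: the two 4-cycles pairings
  g <- tiny_graph(c("A-B", "B-C", "C-D", "D-A"))
  seen <- unique(vapply(1:100, function(s) {
    e <- graph_edges(rewire_degree_preserving(g, n_swaps = 40, seed = s))
    paste(paste(e$from, e$to), collapse = ";")
  }, character(1)))
  expect_gte(length(seen), 2)
  # every realisation preserves all degrees at 2
  expect_true(all(vapply(1:20, function(s) {
    all(igraph::degree(rewire_degree_preserving(g, n_swaps = 40, seed = s)) == 2)
  }, logical(1))))
})

test_that("edge perturbation models change exactly the rounded edge count", {
  net <- generate_modular_network(module_size = 12, seed = 5)
  g <- net$graph
  m <- igraph::ecount(g)
  expect_equal(igraph::ecount(perturb_edges(g, "add_random", 0.1, seed = 1)),
               m + round(0.1 * m))
  expect_equal(igraph::ecount(perturb_edges(g, "remove_random", 0.1, seed = 1)),
               m - round(0.1 * m))
  expect_equal(igraph::ecount(perturb_edges(g, "add_preferential", 0.1, seed = 1)),
               m + round(0.1 * m))
  # fraction 0 is a no-op; complete graphs cannot take additions
  expect_equal(igraph::ecount(perturb_edges(g, "add_random", 0, seed = 1)), m)
  k4 <- tiny_graph(c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D"))
  expect_error(perturb_edges(k4, "add_random", 0.5, seed = 1), "no room")
})

test_that("add then remove at the same fraction restores the edge count", {
  net <- generate_modular_network(module_size = 10, seed = 6)
  g <- net$graph
  m <- igraph::ecount(g)
  added <- perturb_edges(g, "add_random", 0.2, seed = 11)
  k <- igraph::ecount(added) - m
  removed <- perturb_edges(added, "remove_random", k / igraph::ecount(added),
                           seed = 12)
  expect_equal(igraph::ecount(removed), m)
})

test_that("preferential addition concentrates new edges on the hub", {
  # star plus a tail: the hub (degree 8) still has room to gain edges
  # toward the tail nodes, and out-draws any degree-1 node
  g <- tiny_graph(c(paste0("hub-l", 1:8),
                    "t1-t2", "t2-t3", "t3-t4", "t4-t5"))
  gains <- stats::setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  for (s in 1:60) {
    p <- perturb_edges(g, "add_preferential", 0.25, seed = s)  # 3 new edges
    gained <- igraph::degree(p)[names(gains)] - igraph::degree(g)[names(gains)]
    gains <- gains + gained
  }
  expect_gt(gains[["hub"]], max(gains[paste0("l", 1:8)]))
})

test_that("stochastic operations are reproducible from their seed", {
  net <- generate_modular_network(module_size = 10, seed = 8)
  g <- net$graph
  for (op in list(
    function(s) rewire_random(g, seed = s),
    function(s) rewire_degree_preserving(g, seed = s),
    function(s) perturb_edges(g, "add_random", 0.1, seed = s),
    function(s) perturb_edges(g, "add_preferential", 0.1, seed = s),
    function(s) perturb_edges(g, "remove_random", 0.1, seed = s))) {
    expect_equal(graph_edges(op(99)), graph_edges(op(99)))
  }
})

test_that("modularity ratio matches a hand-counted mixed graph", {
  # u1,u2,u3 in c1; v1,v2,v3 in c2
  # edges: u1-u2, u2-u3 (same), v1-v2 (same), u1-v1, u3-v3 (diff)
  # E_same=3, E_diff=2, P_same=2*C(3,2)=6, P_diff=9
  # L = (3/6)/(2/9) = 2.25 ; raw edge ratio 3/2
  g <- tiny_graph(c("u1-u2", "u2-u3", "v1-v2", "u1-v1", "u3-v3"),
                  annotations = c(u1 = "c1", u2 = "c1", u3 = "c1",
                                  v1 = "c2", v2 = "c2", v3 = "c2"))
  mc <- modularity_counts(g)
  expect_equal(mc$e_same, 3); expect_equal(mc$e_diff, 2)
  expect_equal(mc$p_same, 6); expect_equal(mc$p_diff, 9)
  expect_equal(mc$ratio, 2.25)
  expect_equal(mc$edge_ratio, 1.5)
  expect_equal(modularity_ratio(g), 2.25)
})

test_that("modularity ratio handles degenerate edge patterns", {
  # only cross-category edges -> 0
  cross <- tiny_graph(c("u1-v1", "u2-v2"),
                      annotations = c(u1 = "c1", u2 = "c1",
                                      v1 = "c2", v2 = "c2"))
  expect_equal(modularity_ratio(cross), 0)
  # no cross-category edges -> flagged infinite
  within <- tiny_graph(c("u1-u2", "v1-v2"),
                       annotations = c(u1 = "c1", u2 = "c1",
                                       v1 = "c2", v2 = "c2"))
  expect_warning(r <- modularity_ratio(within), "infinite")
  expect_true(is.infinite(r))
  # pair universe without unshared pairs -> error
  same_only <- tiny_graph("u1-u2", annotations = c(u1 = "c1", u2 = "c1"))
  expect_error(modularity_ratio(same_only), "pair universe")
})

test_that("null distribution applies the add-one empirical p-value", {
  net <- generate_modular_network(module_size = 10, seed = 13)
  g <- largest_component(net$graph)
  nd <- null_distribution(g, n_replicates = 100, seed = 21)
  # strongly modular planted graph beats every rewired null
  expect_equal(nd$empirical_p, 1 / 101)
  expect_gt(nd$observed_ratio, nd$null_mean)
  expect_gte(nd$empirical_p, 1 / (nd$n_replicates + 1))
  expect_equal(glance(nd)$null_mean, mean(tidy(nd)$null_ratio))
  # annotation-free graphs have no modularity to measure
  bare <- tiny_graph(c("A-B", "B-C", "C-D"))
  expect_error(null_distribution(bare, n_replicates = 5), "annotated")
})

test_that("robustness protocol is exact for a zero perturbation", {
  net <- generate_modular_network(module_size = 12, seed = 14)
  g <- largest_component(net$graph)
  rs <- robustness_summary(g, "cat1", "add_random", fraction = 0,
                           n_replicates = 5, seed = 30)
  expect_equal(rs$sd_rank, rep(0, nrow(rs)))
  expect_equal(rs$mean_rank, rs$rank_unperturbed)
  expect_true(all(rs$freq_top10 %in% c(0, 1)))
})

test_that("top-10% membership frequency never exceeds top-20% frequency", {
  net <- generate_modular_network(module_size = 12, seed = 15)
  g <- largest_component(net$graph)
  rs <- robustness_summary(g, "cat2", "add_random", 0.1,
                           n_replicates = 15, seed = 40)
  expect_true(all(rs$freq_top10 <= rs$freq_top20))
  expect_equal(attr(rs, "n_replicates"), 15)
  # betweenness-rank variant obeys the same invariant
  rb <- robustness_summary(g, "cat2", "remove_random", 0.1,
                           n_replicates = 10, seed = 50,
                           rank_by = "betweenness")
  expect_true(all(rb$freq_top10 <= rb$freq_top20))
})
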