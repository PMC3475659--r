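test_that("linkerity is the sub-network rank over the core rank", {
  expect_equal(round_display(linkerity_score(73.5, 8)), 9.19)
  expect_equal(linkerity_score(35, 5), 7)
  expect_equal(linkerity_score(17, 17), 1)
  expect_equal(linkerity_score(c(12, 64), c(3, 16)), c(4, 4))
  expect_error(linkerity_score(5, 0), "rank_core")
  expect_error(linkerity_score(0, 5), "rank_sub")
})

test_that("core ranking restricts to members after full-graph betweenness", {
  fx <- toy_linker_fixture()
  core <- largest_component(fx$graph)
  # all-node restriction is the plain core ranking
  all_rank <- rank_in_core(core, igraph::V(core)$name)
  direct <- average_rank(betweenness_scores(core))
  expect_equal(all_rank, direct, ignore_attr = TRUE)
  # two members keep their relative order from core BC
  two <- rank_in_core(core, c("A4", "A1"))
  expect_equal(stats::setNames(two$rank, two$node), c(A4 = 1, A1 = 2))
  # members outside the core component are excluded with a message
  g <- tiny_graph(c("A-B", "B-C", "X-Y"))
  expect_message(r <- rank_in_core(g, c("A", "B", "X")), "excluded")
  expect_setequal(r$node, c("A", "B"))
})

test_that("toy fixture reproduces its frozen linkerity table exactly", {
  fx <- toy_linker_fixture()
  lt <- linkerity_table(largest_component(fx$graph), "alpha")
  expect_equal(as.data.frame(lt), as.data.frame(fx$expected),
               tolerance = 1e-12)
  # the planted linker dominates; the local hub does not
  expect_equal(lt$node[1], "L")
  expect_gt(lt$linkerity[1], max(lt$linkerity[-1]))
  expect_lte(lt$linkerity[lt$node == "A4"], 1)
  # the non-bridging category is rank-stable: everything at exactly 1
  lb <- linkerity_table(largest_component(fx$graph), "beta")
  expect_equal(lb$linkerity, rep(1, nrow(lb)))
})

test_that("a single-category core yields linkerity 1 for every node", {
  set.seed(41)
  g <- random_connected_graph(12)
  ann <- tibble::tibble(node = igraph::V(g)$name, category = "only")
  g <- linkerity:::set_annotations(g, ann)
  lt <- linkerity_table(g, "only")
  expect_equal(lt$linkerity, rep(1, nrow(lt)))
  expect_equal(lt$rank_sub, lt$rank_core)
})

test_that("linkerity table matches a step-by-step manual pipeline", {
  # 15-node two-module fixture, assembled by hand
  edges <- c("A-B", "A-C", "B-C", "B-D", "C-D", "D-E", "E-F", "A-F",
             "P-Q", "P-R", "Q-R", "Q-S", "R-S", "S-T",
             "E-P",          # direct inter-module edge
             "F-bridge", "bridge-T", "bridge-P")  # planted bridge, category 1
  ann <- c(A = "m1", B = "m1", C = "m1", D = "m1", E = "m1", F = "m1",
           bridge = "m1",
           P = "m2", Q = "m2", R = "m2", S = "m2", T = "m2")
  g <- largest_component(tiny_graph(edges, annotations = ann))
  lt <- linkerity_table(g, "m1")
  # manual pipeline with the independent betweenness oracle and base rank
  members <- names(ann)[ann == "m1"]
  sub <- igraph::induced_subgraph(g, members)
  bc_sub <- oracle_betweenness(linkerity:::as_annotated(sub))
  rank_sub <- rank(-bc_sub, ties.method = "average")
  bc_core <- oracle_betweenness(g)[members]
  rank_core <- rank(-bc_core, ties.method = "average")
  manual <- tibble::tibble(node = members,
                           rank_sub = unname(rank_sub[members]),
                           rank_core = unname(rank_core[members]),
                           linkerity = unname(rank_sub / rank_core))
  joined <- merge(as.data.frame(lt), manual, by = "node",
                  suffixes = c("", ".manual"))
  expect_equal(nrow(joined), length(members))
  expect_equal(joined$rank_sub, joined$rank_sub.manual)
  expect_equal(joined$rank_core, joined$rank_core.manual)
  expect_equal(joined$linkerity, joined$linkerity.manual, tolerance = 1e-12)
})

test_that("linkerity values are invariant under node relabeling", {
  net <- generate_modular_network(module_size = 15, seed = 9)
  g <- largest_component(net$graph)
  nodes <- igraph::V(g)$name
  set.seed(1)
  relabel <- stats::setNames(sprintf("z%03d", sample(length(nodes))), nodes)
  rec <- graph_edges(g)
  rec2 <- tibble::tibble(protein_a = unname(relabel[rec$from]),
                         protein_b = unname(relabel[rec$to]),
                         confidence = 1)
  ann <- tidyr::unnest(graph_nodes(g), "categories")
  ann2 <- tibble::tibble(node = unname(relabel[ann$node]),
                         category = ann$categories)
  g2 <- largest_component(build_graph(rec2, ann2))
  lt1 <- linkerity_table(g, "cat1")
  lt2 <- linkerity_table(g2, "cat1")
  expect_equal(stats::setNames(lt2$linkerity, lt2$node)[unname(relabel[lt1$node])],
               stats::setNames(lt1$linkerity, unname(relabel[lt1$node])))
})

test_that("a too-small category sub-network is an error", {
  g <- tiny_graph(c("A-B", "B-C", "C-D"),
                  annotations = c(A = "big", B = "big", C = "big", D = "tiny"))
  expect_error(linkerity_table(g, "tiny"), ">= 3")
  expect_error(linkerity_table(g, "absent"), "not present")
})

test_that("planted linkers top the linkerity ranking on the default fixture", {
  # smaller replicate count here; the full 100-replicate protocol runs in
  # the acceptance suite
  hits <- 0
  for (s in 1:15) {
    net <- generate_modular_network(seed = s)
    g <- largest_component(net$graph)
    ok <- all(vapply(category_universe(g), function(cat) {
      lt <- linkerity_table(g, cat)
      planted <- intersect(net$truth$planted_linkers,
                           lt$node[lt$categories == cat])
      all(planted %in% lt$node[seq_along(planted)])
    }, logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits, 14)
})
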