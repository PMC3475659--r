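test_that("betweenness matches closed forms on paths and stars", {
  path <- tiny_graph(c("A-B", "B-C"))
  bc <- betweenness_scores(path)
  expect_equal(bc$score[bc$node == "B"], 1)
  expect_equal(bc$score[bc$node != "B"], c(0, 0))
  star <- tiny_graph(paste0("hub-l", 1:5))
  bs <- betweenness_scores(star)
  expect_equal(bs$score[bs$node == "hub"], 5 * 4 / 2)
  # below 3 nodes every score is 0
  expect_equal(betweenness_scores(tiny_graph("A-B"))$score, c(0, 0))
})

test_that("betweenness equals the all-geodesics enumeration oracle", {
  set.seed(101)
  for (i in 1:30) {
    g <- random_connected_graph(sample(5:12, 1))
    got <- betweenness_scores(g)
    oracle <- oracle_betweenness(g)
    expect_equal(stats::setNames(got$score, got$node)[names(oracle)],
                 oracle, tolerance = 1e-10)
  }
})

test_that("average ranking follows the worked six-protein example", {
  rt <- average_rank(c(A = 10, B = 10, C = 7, D = 5, E = 5, F = 5))
  expect_equal(rt$rank, c(1.5, 1.5, 3, 5, 5, 5))
  expect_equal(rt$node, c("A", "B", "C", "D", "E", "F"))
  # complete tie and no tie
  expect_equal(average_rank(c(x = 1, y = 1, z = 1))$rank, c(2, 2, 2))
  rt2 <- average_rank(c(a = 5, b = 2, c = 9))
  expect_equal(stats::setNames(rt2$rank, rt2$node)[c("a", "b", "c")],
               c(a = 2, b = 3, c = 1))
  expect_equal(nrow(average_rank(numeric(0))), 0)
})

test_that("rank sum is n(n+1)/2 and ranking survives monotone transforms", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    scores <- stats::setNames(sample(0:8, n, replace = TRUE), sprintf("v%02d", 1:n))
    rt <- average_rank(scores)
    expect_equal(sum(rt$rank), n * (n + 1) / 2)
    # any positive monotone transform leaves the ranks unchanged
    transformed <- average_rank(exp(scores / 3) + 1)
    expect_equal(stats::setNames(transformed$rank, transformed$node)[rt$node],
                 stats::setNames(rt$rank, rt$node))
  }
})

test_that("top-fraction selection respects quota and tie policy", {
  rt <- average_rank(stats::setNames(c(10:1), sprintf("n%02d", 1:10)))
  expect_equal(length(top_fraction(rt, 0.2)), 2)
  expect_setequal(top_fraction(rt, 1.0), rt$node)
  # worked example: 6 proteins, top half
  rt6 <- average_rank(c(A = 10, B = 10, C = 7, D = 5, E = 5, F = 5))
  expect_setequal(top_fraction(rt6, 0.5), c("A", "B", "C"))
  # straddling tie group resolved by identifier order
  rtie <- average_rank(c(b = 5, a = 5, c = 5, d = 1))
  expect_setequal(top_fraction(rtie, 0.5), c("a", "b"))
  expect_error(top_fraction(rt, 0), "fraction")
})

test_that("essentiality enrichment reports percentages over labelled nodes", {
  labels <- tibble::tibble(node = sprintf("n%d", 1:6),
                           lethality = c("E", "E", "E", "E", "E", "V"))
  expect_equal(essentiality_enrichment(sprintf("n%d", 1:5), labels)$pct_essential,
               100)
  r <- essentiality_enrichment(c("n3", "n4", "n5", "n6"),
                               tibble::tibble(node = sprintf("n%d", 3:6),
                                              lethality = c("E", "V", "V", "V")))
  expect_equal(r$pct_essential, 25)
  expect_error(essentiality_enrichment("zz", labels), "label")
})

test_that("degree-planted essentiality enriches hubs above the global rate", {
  net <- generate_modular_network(seed = 19)
  g <- largest_component(net$graph)
  hubs <- top_fraction(average_rank(degree_scores(g)), 0.2)
  hub_rate <- essentiality_enrichment(hubs, net$lethality)$pct_essential
  global_rate <- essentiality_enrichment(igraph::V(g)$name,
                                         net$lethality)$pct_essential
  expect_gt(hub_rate, global_rate)
})

test_that("power-law fit recovers a noiseless exponent and rejects thin input", {
  h <- tibble::tibble(degree = 1:50, frequency = (1:50)^-2)
  fit <- fit_power_law(h)
  expect_equal(fit$gamma, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_power_law(tibble::tibble(degree = 1:2,
                                            frequency = c(0.5, 0.125))),
               "3 positive-frequency")
  # preferential-attachment degrees give a heavy-tail exponent in range
  g <- generate_scale_free(2000, attach = 2, seed = 5)
  fit_pa <- fit_power_law(as.numeric(igraph::degree(g)))
  expect_gt(fit_pa$gamma, 1.8)
  expect_lt(fit_pa$gamma, 3.5)
  # broom-style accessors agree with the object
  expect_equal(glance(fit)$gamma, fit$gamma)
  expect_equal(nrow(tidy(fit)), fit$n_bins)
})
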