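test_that("k-means recovers well-separated blobs and picks k = 2", {
  em <- blob_expression(n_per_blob = 20, n_blobs = 2, n_samples = 24,
                        sep = 10, seed = 31)
  cfg <- swim_config(k_min = 2, k_max = 6, kmeans_replicates = 10, seed = 1)
  part <- cluster_expression(em, gene_ids(em), cfg)
  expect_equal(part$k, 2L)
  truth <- rep(1:2, each = 20)
  tab <- table(part$assignment, truth)
  # agreement up to label permutation
  expect_equal(sum(apply(tab, 1, max)), 40)
})

test_that("clustering is deterministic and its SSE trace non-increasing", {
  em <- blob_expression(n_per_blob = 8, n_blobs = 3, sep = 4, seed = 32)
  cfg <- swim_config(k_min = 2, k_max = 8, kmeans_replicates = 5, seed = 9)
  p1 <- cluster_expression(em, gene_ids(em), cfg)
  p2 <- cluster_expression(em, gene_ids(em), cfg)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$sse_trace) <= 1e-9))
  expect_error(cluster_expression(em, gene_ids(em),
                                  swim_config(k_min = 2, k_max = 100)),
               "k_max")
})

test_that("cartography quantities match their definitions on toy graphs", {
  # node with all edges internal -> Kpi = 0; all external -> Kpi = 1
  nodes <- c("a", "b", "c", "d")
  edges <- data.frame(gene_a = c("a", "a", "c"), gene_b = c("b", "c", "d"),
                      r = c(0.9, 0.8, -0.5))
  net <- coexpression_network(nodes, edges)
  part <- list(assignment = c(a = 1L, b = 1L, c = 2L, d = 2L), k = 2L)
  cart <- compute_cartography(net, part)
  rownames(cart) <- cart$gene
  expect_equal(cart["b", "kpi"], 0)        # single edge, internal
  expect_equal(cart["a", "kpi"], 1 - (1 / 2)^2)
  expect_equal(cart["d", "kpi"], 0)        # c-d internal
  # APCC: mean of incident edge correlations
  expect_equal(cart["c", "apcc"], mean(c(0.8, -0.5)))
  expect_equal(cart["a", "apcc"], mean(c(0.9, 0.8)))

  # Zg arithmetic: kappa = 5 in a module with mean 3, sd 1 -> Zg = 2
  kappa <- c(5, 3, 2, 4, 2, 2)  # mean 3, sd sqrt(6/5)... construct directly
  zg <- (kappa - mean(kappa)) / sd(kappa)
  expect_equal(zg[1], (5 - 3) / sd(kappa))
})

test_that("cartography equals the brute-force oracle on random graphs", {
  for (seed in 1:6) {
    g <- random_edge_graph(n = 5 + seed * 3, p = 0.3, seed = seed)
    net <- coexpression_network(g$nodes, g$edges)
    withr::with_seed(seed, {
      assignment <- setNames(sample(1:3, length(g$nodes), replace = TRUE),
                             g$nodes)
    })
    part <- list(assignment = assignment, k = 3L)
    cart <- compute_cartography(net, part)
    oracle <- oracle_cartography(g$nodes, g$edges, assignment)
    expect_equal(cart$degree, oracle$degree)
    expect_equal(cart$internal_degree, oracle$internal_degree)
    expect_equal(cart$zg, oracle$zg, tolerance = 1e-12)
    expect_equal(cart$kpi, oracle$kpi, tolerance = 1e-12)
    expect_equal(cart$apcc, oracle$apcc, tolerance = 1e-12)
  }
})

test_that("printed decision rules classify hubs, regions and switch genes", {
  cart <- data.frame(
    gene = c("sw", "hub", "pos"),
    module = 1L, degree = 5L, internal_degree = 1L,
    zg = c(1.0, 6.0, 1.0),
    kpi = c(0.9, 0.9, 0.9),
    apcc = c(-0.3, -0.3, 0.3)
  )
  out <- classify_nodes(cart, swim_config())
  expect_equal(out$is_switch, c(TRUE, FALSE, FALSE))
  expect_equal(out$hub, c(FALSE, TRUE, FALSE))
  expect_equal(out$hub_class, c("fight_club", "fight_club", "date"))
  expect_equal(out$region[1], "R4")
})

test_that("switch extraction orders by ascending APCC and handles edge cases", {
  cart <- data.frame(
    gene = c("a", "b", "c"), module = 1L, degree = 3L, internal_degree = 0L,
    zg = 0, kpi = 0.95, apcc = c(-0.2, -0.7, 0.4)
  )
  out <- classify_nodes(cart, swim_config())
  expect_equal(extract_switch_genes(out), c("b", "a"))

  none <- cart
  none$apcc <- abs(none$apcc)
  expect_length(extract_switch_genes(classify_nodes(none, swim_config())), 0)

  all_sw <- cart
  all_sw$apcc <- c(-0.1, -0.1, -0.5)
  expect_equal(extract_switch_genes(classify_nodes(all_sw, swim_config())),
               c("c", "a", "b"))
})

test_that("average shortest path matches closed forms and the oracle", {
  path3 <- coexpression_network(c("a", "b", "c"),
                                data.frame(gene_a = c("a", "b"),
                                           gene_b = c("b", "c"), r = 0.9))
  expect_equal(average_shortest_path(path3), 4 / 3)

  k4_edges <- t(combn(letters[1:4], 2))
  k4 <- coexpression_network(letters[1:4],
                             data.frame(gene_a = k4_edges[, 1],
                                        gene_b = k4_edges[, 2], r = 0.8))
  expect_equal(average_shortest_path(k4), 1)

  g <- random_edge_graph(12, 0.25, seed = 77)
  net <- coexpression_network(g$nodes, g$edges)
  expect_equal(average_shortest_path(net), oracle_asp(g$nodes, g$edges),
               tolerance = 1e-12)

  lonely <- coexpression_network(c("a", "b"),
                                 data.frame(gene_a = character(),
                                            gene_b = character(),
                                            r = numeric()),
                                 corr_threshold = 0.7)
  expect_warning(asp <- average_shortest_path(lonely), "single node")
  expect_equal(asp, 0)
})

test_that("robustness curves share their starting point and terminate", {
  g <- random_edge_graph(20, 0.3, seed = 41)
  net <- coexpression_network(g$nodes, g$edges)
  part <- list(assignment = setNames(rep(1:2, 10), g$nodes), k = 2L)
  cart <- classify_nodes(compute_cartography(net, part), swim_config())
  rb <- robustness_analysis(net, cart, step = 0.1, reps = 3, seed = 4)
  at0 <- rb$avg_shortest_path[rb$fraction_removed == 0]
  expect_length(at0, 5)
  expect_true(all(at0 == at0[1]))
  expect_setequal(unique(rb$strategy),
                  c("date", "party", "fight_club", "switch", "random"))

  tiny <- coexpression_network(c("a", "b"),
                               data.frame(gene_a = "a", gene_b = "b", r = 0.9))
  part2 <- list(assignment = c(a = 1L, b = 1L), k = 1L)
  cart2 <- classify_nodes(compute_cartography(tiny, part2), swim_config())
  rb2 <- robustness_analysis(tiny, cart2, step = 0.1, reps = 2, seed = 1)
  # removing a node would leave < 2: the curve terminates before 50%
  expect_lt(max(rb2$fraction_removed), 0.5)
  expect_true(all(rb2$avg_shortest_path == 1))
})

test_that("biclustering orders are deterministic and group identical rows", {
  vals <- rbind(
    r1 = c(1, 2, 3, 4, 5, 6),
    r2 = c(9, 1, 4, 4, 2, 8),
    r3 = c(1, 2, 3, 4, 5, 6),  # identical to r1
    r4 = c(6, 5, 4, 3, 2, 1)
  )
  colnames(vals) <- sprintf("s%d", 1:6)
  em <- expression_matrix(vals, "log2")
  ord <- bicluster_order(em)
  pos <- match(c(1, 3), ord$row_order)
  expect_equal(abs(diff(pos)), 1)  # identical rows adjacent

  one <- expression_matrix(vals[1, , drop = FALSE], "log2")
  expect_equal(bicluster_order(one)$row_order, 1)

  withr::with_seed(55, {
    v6 <- matrix(rnorm(36), 6, dimnames = list(sprintf("g%d", 1:6),
                                               sprintf("s%d", 1:6)))
  })
  em6 <- expression_matrix(v6, "log2")
  expect_identical(bicluster_order(em6), bicluster_order(em6))
})
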