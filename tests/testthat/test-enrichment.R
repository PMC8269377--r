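test_that("hypergeometric p-values are exact", {
  # N = 10, K = 5, n = 5, x = 5 -> 1/252
  expect_equal(ora_pvalue(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  # x = 0 -> certain event, p = 1
  expect_equal(ora_pvalue(0, 5, 5, 10), 1)
  # enumeration oracle across all (N <= 30, K, n, x) on a grid of N
  for (N in c(2, 5, 9, 17, 30)) {
    for (K in 0:N) {
      for (n in 0:N) {
        xs <- max(0, n + K - N):min(K, n)
        for (x in xs) {
          expect_equal(ora_pvalue(x, K, n, N), oracle_hyper_p(x, K, n, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("ORA tables are well-formed and label-invariant", {
  universe <- sprintf("g%02d", 1:20)
  sets <- gene_set_collection(list(
    hit = universe[1:5],
    miss = universe[11:18],
    all = universe
  ))
  query <- universe[1:5]
  tab <- ora_enrichment(query, sets, universe)
  expect_equal(tab$overlap[tab$set == "hit"], 5L)
  expect_equal(tab$p_value[tab$set == "all"], 1)  # set == universe -> certain
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(all(tab$q_value >= tab$p_value))
  expect_true(all(tab$overlap <= pmin(tab$set_size, tab$query_size)))

  # permuting gene labels leaves the p-values unchanged
  withr::with_seed(8, perm <- setNames(sample(universe), universe))
  sets_p <- gene_set_collection(lapply(unclass(sets), function(s) unname(perm[s])))
  tab_p <- ora_enrichment(unname(perm[query]), sets_p, unname(perm[universe]))
  expect_equal(tab_p$p_value[match(tab$set, tab_p$set)], tab$p_value,
               tolerance = 1e-12)

  expect_error(ora_enrichment(character(), sets, universe), "empty query")
  expect_error(ora_enrichment("not_there", sets, universe), "outside")
})

test_that("minimum connected subnetwork keeps the largest seed component", {
  # seed "a" has three interactors -> star of four nodes
  it <- interaction_table(
    source = c("a", "a", "a", "f"),
    target = c("b", "c", "d", "g"),
    kind = "gene")
  star <- minimum_connected_subnetwork("a", it)
  expect_setequal(star$nodes, c("a", "b", "c", "d"))

  # seeds in disconnected components of sizes 4 and 2: the larger one wins
  two <- minimum_connected_subnetwork(c("a", "f"), it)
  expect_setequal(two$nodes, c("a", "b", "c", "d"))
  expect_equal(minimum_connected_subnetwork(c("a", "zz"), it)$missing_seeds,
               "zz")

  # oracle: seeds + first neighbors, then the largest component by BFS
  g <- random_edge_graph(15, 0.15, seed = 19)
  it2 <- interaction_table(g$edges$gene_a, g$edges$gene_b,
                           rep("gene", nrow(g$edges)))
  seeds <- g$nodes[c(1, 5, 9)]
  seeds <- intersect(seeds, unique(c(it2$source, it2$target)))
  mcs <- minimum_connected_subnetwork(seeds, it2)
  adj <- oracle_adjacency(g$nodes, g$edges)$adj
  nbrs <- unique(c(seeds, unlist(lapply(seeds, function(s) {
    g$nodes[adj[s, ] == 1]
  }))))
  sub_adj <- adj[nbrs, nbrs, drop = FALSE]
  # BFS components on the induced set
  comp <- rep(NA_integer_, length(nbrs)); cid <- 0
  for (i in seq_along(nbrs)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(sub_adj[v, ] == 1 & is.na(comp)))
    }
  }
  expected <- sort(nbrs[comp == which.max(tabulate(comp))])
  expect_equal(mcs$nodes, expected)
})

test_that("betweenness matches closed forms and the enumeration oracle", {
  path3 <- coexpression_network(c("a", "b", "c"),
                                data.frame(gene_a = c("a", "b"),
                                           gene_b = c("b", "c"), r = 0.9))
  b <- betweenness_centrality(path3)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))

  k5_edges <- t(combn(letters[1:5], 2))
  k5 <- coexpression_network(letters[1:5],
                             data.frame(gene_a = k5_edges[, 1],
                                        gene_b = k5_edges[, 2], r = 0.9))
  expect_true(all(betweenness_centrality(k5) == 0))

  for (seed in 1:8) {
    g <- random_edge_graph(n = 5 + (seed %% 4), p = 0.4, seed = 100 + seed)
    net <- coexpression_network(g$nodes, g$edges)
    b <- betweenness_centrality(net)
    oracle <- oracle_betweenness(g$nodes, g$edges)
    expect_equal(unname(b[g$nodes]), unname(oracle), tolerance = 1e-10)
  }
})

test_that("regulator ranking is total, deterministic and tie-aware", {
  it <- interaction_table(
    source = c("TF_A", "TF_A", "TF_A", "TF_B"),
    target = c("s1", "s2", "s3", "s1"),
    kind = "tf")
  rk <- rank_regulators(c("s1", "s2", "s3"), it, "tf")
  expect_equal(rk$source[rk$rank == 1], "TF_A")
  expect_equal(sort(rk$rank), seq_len(nrow(rk)))

  # path TF_X - s2 - TF_Z - s3 - TF_Y: all degrees 2, TF_Z most central
  it2 <- interaction_table(
    source = c("TF_X", "TF_X", "TF_Y", "TF_Y", "TF_Z", "TF_Z"),
    target = c("s1", "s2", "s3", "s4", "s2", "s3"),
    kind = rep("tf", 6))
  rk2 <- rank_regulators(paste0("s", 1:4), it2, "tf")
  expect_true(all(rk2$degree == 2))
  expect_equal(rk2$source[rk2$rank == 1], "TF_Z")
  expect_equal(rk2$source, c("TF_Z", "TF_X", "TF_Y"))  # name tie-break X < Y
  expect_error(rank_regulators("s1", it, "chemical"), "no interactions")
})

test_that("the planted high-degree regulator ranks first across seeds", {
  hits <- 0
  for (s in 1:20) {
    d <- generate_dataset(sim_config(seed = s))
    it <- generate_interaction_table(d$truth, n_regulators = 10, seed = s)
    rk <- rank_regulators(d$truth$gene[d$truth$is_switch], it, "tf")
    hits <- hits + (rk$source[rk$rank == 1] == attr(it, "planted_regulator"))
  }
  expect_gte(hits / 20, 0.9)
})
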