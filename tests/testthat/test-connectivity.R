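synapse_df <- function(pre, post, kind = rep("basal", length(pre)), n_neurons = 4) {
  k <- length(pre)
  df <- data.frame(pre = pre, post = post,
                   axonal_piece = seq_len(k), dendritic_piece = seq_len(k),
                   x = rep(0, k), y = rep(0, k), z = rep(0, k),
                   orth_dist = rep(1, k), post_kind = kind,
                   pre_path_dist = rep(1, k), post_path_dist = rep(1, k),
                   pre_eucl_dist = rep(1, k), post_eucl_dist = rep(1, k))
  attr(df, "n_neurons") <- n_neurons
  df
}

test_that("build_graph aggregates synapses into weighted connections", {
  g <- build_graph(synapse_df(integer(0), integer(0)), n_neurons = 5)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 0)
  g <- build_graph(synapse_df(c(1, 1, 1), c(2, 2, 2)), n_neurons = 3)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 3L)
  expect_equal(connection_strength_stats(g)$mean, 3)
  # connection probability identities (directed and undirected views)
  g2 <- build_graph(synapse_df(c(1, 2, 3, 1), c(2, 1, 4, 3)), n_neurons = 4)
  expect_equal(connection_probability(g2), 4 / 12)
  expect_equal(connection_probability(g2, "undirected"),
               igraph::ecount(arborsim:::undirected_view(g2)) / 6)
})

test_that("the worked 4-node example gives L = 1.3333 and C = 0.5833", {
  g <- worked_example_graph()
  expect_equal(mean_shortest_path(g), 4 / 3, tolerance = 1e-9)
  expect_equal(clustering_coefficient(g), 7 / 12, tolerance = 1e-9)
})

test_that("graph metrics agree with exhaustive oracles on random graphs", {
  set.seed(71)
  for (rep in 1:8) {
    n <- sample(10:30, 1)
    repeat {
      g <- igraph::sample_gnp(n, runif(1, 0.15, 0.5))
      if (igraph::is_connected(g)) break
    }
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_equal(mean_shortest_path(g), floyd_warshall_mean(adj), tolerance = 1e-12)
    expect_equal(clustering_coefficient(g), naive_clustering(adj), tolerance = 1e-12)
  }
  # degenerate shapes
  tri <- igraph::make_full_graph(3)
  expect_equal(clustering_coefficient(tri), 1)
  expect_equal(mean_shortest_path(igraph::make_full_graph(6)), 1)
  tree <- igraph::make_tree(10, children = 2, mode = "undirected")
  expect_equal(clustering_coefficient(tree), 0)
  expect_error(mean_shortest_path(igraph::make_empty_graph(3, directed = FALSE)),
               "not connected")
})

test_that("degree distributions satisfy conservation and the star-graph example", {
  syn <- synapse_df(c(1, 1, 1), c(2, 3, 4))
  g <- build_graph(syn, n_neurons = 4)
  dd <- degree_distributions(g)
  expect_equal(dd$all$out_degree, c(3, 0, 0, 0))
  expect_equal(dd$all$in_degree, c(0, 1, 1, 1))
  expect_equal(sum(dd$all$in_degree), sum(dd$all$out_degree)) # handshake
  # kind splitting: connections with >= 1 synapse of the kind
  syn2 <- synapse_df(c(1, 1, 2), c(2, 3, 3), kind = c("basal", "apical", "basal"))
  dd2 <- degree_distributions(build_graph(syn2, n_neurons = 3))
  expect_equal(sum(dd2$basal$out_degree), 2)
  expect_equal(sum(dd2$apical$out_degree), 1)
})

test_that("connection probability vs distance matches brute-force enumeration", {
  soma <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 30, 0), c(50, 0, 0))
  syn <- synapse_df(c(1, 2, 1), c(2, 1, 3))
  g <- build_graph(syn, n_neurons = 4)
  out <- connection_probability_vs_distance(g, soma, bin_width = 20,
                                            mode = "undirected")
  # pairwise distances: 10 | 30, 31.6 | 50, 40, 58.3; connected pairs: 1-2, 1-3
  expect_equal(out$n_pairs, c(1, 2, 3))
  expect_equal(out$probability, c(1, 1 / 2, 0))
  outd <- connection_probability_vs_distance(g, soma, bin_width = 20)
  expect_equal(outd$n_pairs, 2 * out$n_pairs)
  expect_equal(outd$n_connected, c(2, 1, 0))
  expect_equal(sum(outd$n_connected), igraph::ecount(g))
  # fully connected toy: every bin at probability 1
  g3 <- build_graph(synapse_df(c(1, 2, 3), c(2, 3, 1), n_neurons = 3), 3)
  out3 <- connection_probability_vs_distance(g3, soma[1:3, ], bin_width = 20,
                                             mode = "undirected")
  expect_true(all(out3$probability == 1))
})

test_that("connection lengths split by pure dendrite kind and conserve counts", {
  soma <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 200, 0))
  syn <- synapse_df(c(1, 1, 2, 1), c(2, 2, 3, 3),
                    kind = c("basal", "basal", "apical", "basal"), n_neurons = 3)
  g <- build_graph(syn, 3)
  cl <- connection_length_distributions(g, soma)
  expect_equal(cl$basal$n, 2)          # 1->2 and 1->3 are pure basal
  expect_equal(cl$apical$n, 1)         # 2->3 pure apical
  expect_equal(cl$mixed$n, 0)
  expect_equal(cl$basal$mean, (100 + 200) / 2)
  expect_equal(cl$apical$mean, sqrt(100^2 + 200^2))
  expect_equal(sum(cl$basal$hist$counts), cl$basal$n)
  # a mixed connection leaves both pure classes
  syn2 <- synapse_df(c(1, 1), c(2, 2), kind = c("basal", "apical"), n_neurons = 2)
  cl2 <- connection_length_distributions(build_graph(syn2, 2), soma[1:2, ])
  expect_equal(cl2$basal$n + cl2$apical$n, 0)
  expect_equal(cl2$mixed$n, 1)
})

test_that("edge randomization preserves size, simplicity and connectivity", {
  set.seed(72)
  g <- worked_example_graph()
  for (i in 1:10) {
    r <- randomize_edges(g)
    expect_equal(igraph::vcount(r), 4)
    expect_equal(igraph::ecount(r), 4)
    expect_true(igraph::is_simple(r))
    expect_true(igraph::is_connected(r))
  }
})

test_that("small-world report: random graphs score ~1, rewired lattices >> 1", {
  set.seed(73)
  # dense Erdos-Renyi: clustering ~ density, L ~ random -> gamma/lambda ~ 1
  g <- igraph::sample_gnp(60, 0.3)
  sw <- small_world_report(g, n_rand = 3)
  expect_equal(sw$small_worldness, 1, tolerance = 0.15)
  expect_equal(sw$gamma / sw$lambda, sw$small_worldness, tolerance = 1e-12)
  # Watts-Strogatz regime: ring lattice with light rewiring
  ws <- igraph::sample_smallworld(1, 100, 5, 0.05)
  ws <- igraph::simplify(ws)
  sw2 <- small_world_report(ws, n_rand = 2)
  expect_gt(sw2$small_worldness, 2)
})

test_that("threshold monotonicity carries over to the connection graph", {
  net <- get_small_network()
  g4 <- build_graph(detect_synapses(net, 4))
  g10 <- build_graph(detect_synapses(net, 10))
  e4 <- igraph::as_edgelist(g4)
  e10 <- igraph::as_edgelist(g10)
  expect_true(all(paste(e4[, 1], e4[, 2]) %in% paste(e10[, 1], e10[, 2])))
})
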