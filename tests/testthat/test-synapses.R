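test_that("segment crossing: the three canonical geometries", {
  # perpendicular skew lines 3 um apart
  r <- segment_pair_crossing(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 3), c(0, 1, 3))
  expect_true(r$crossing)
  expect_equal(r$distance, 3)
  expect_equal(r$midpoint, c(0, 0, 1.5))
  # parallel pieces never cross, regardless of distance
  r <- segment_pair_crossing(c(-1, 0, 0), c(1, 0, 0), c(-1, 0, 2), c(1, 0, 2))
  expect_false(r$crossing)
  # closest approach beyond the axonal piece's extent
  r <- segment_pair_crossing(c(-1, 0, 0), c(1, 0, 0), c(5, -1, 1), c(5, 1, 1))
  expect_false(r$crossing)
  # endpoint contact is not an interior crossing
  r <- segment_pair_crossing(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(1, 0, -1))
  expect_false(r$crossing)
  expect_warning(segment_pair_crossing(c(0, 0, 0), c(0, 0, 0),
                                       c(0, 1, 0), c(0, -1, 0)), "zero-length")
})

# two hand-built neurons engineered to share exactly 3 qualifying crossings:
# neuron 1's axon runs along x at z = 2 and crosses three rungs of neuron 2's
# comb-shaped dendrite (orthogonal distances 1, 2, 3), plus one rung at
# distance 10 that never qualifies at threshold 4. The comb's root sits at
# y = -30, so the arms connecting root to rungs stay clear of the axon (their
# line-line closest approach falls beyond the arm segments).
comb_fixture <- function() {
  # axon nodes at x = -42, -37, ..., 43 so the rung crossings at x = 0, 10,
  # 20, 30 fall strictly inside pieces
  xs <- seq(-42, 43, by = 5)
  ax1 <- make_tree(cbind(x = xs, y = 0, z = 2),
                   c(0L, seq_len(length(xs) - 1L)), "axon")
  rungs <- list(c(0, 1), c(10, 2), c(20, 3), c(30, 10))
  pos <- matrix(c(0, -30, 0), 1, 3)
  parent <- 0L
  for (r in rungs) {
    pos <- rbind(pos, c(r[1], -5, 2 - r[2]), c(r[1], 5, 2 - r[2]))
    parent <- c(parent, 1L, nrow(pos) - 1L)
  }
  den2 <- make_tree(pos, parent, "basal")
  ax2 <- make_tree(cbind(x = 0, y = seq(200, 210, by = 5), z = 200),
                   c(0L, 1L, 2L), "axon")
  den1 <- make_tree(cbind(x = seq(100, 110, by = 5), y = 50, z = -50),
                    c(0L, 1L, 2L), "basal")
  toy_network(list(ax1, ax2), list(den1, den2),
              soma = rbind(c(-42, 0, 2), c(0, -30, 0)))
}

test_that("a constructed two-neuron fixture yields exactly 3 synapses", {
  net <- comb_fixture()
  syn <- detect_synapses(net, threshold = 4)
  expect_equal(nrow(syn), 3L)
  expect_true(all(syn$pre == 1L & syn$post == 2L))
  expect_equal(sort(syn$orth_dist), c(1, 2, 3))
  expect_true(all(syn$post_kind == "basal"))
  # synapse locations sit midway between axon (z = 2) and each rung
  expect_equal(sort(syn$z), c(2 - 3 / 2, 2 - 2 / 2, 2 - 1 / 2))
  # Euclidean <= path on both sides
  expect_true(all(syn$post_eucl_dist <= syn$post_path_dist + 1e-9))
  expect_true(all(syn$pre_eucl_dist <= syn$pre_path_dist + 1e-9))
  # threshold 11 picks up the fourth rung
  expect_equal(nrow(detect_synapses(net, threshold = 11)), 4L)
})

test_that("the spatial grid reproduces the all-pairs oracle exactly", {
  gp <- fast_growth_params(days = 8)
  for (seed in c(61, 62)) {
    net <- grow_network(network_config(n_neurons = 8), gp, seed = seed)
    for (th in c(4, 8)) {
      a <- detect_synapses(net, th, method = "grid")
      b <- detect_synapses(net, th, method = "exhaustive")
      expect_gt(nrow(a) + nrow(b), 0)
      expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
    }
  }
})

test_that("synapse sets are monotone in the threshold", {
  net <- get_small_network()
  keyify <- function(s) paste(s$axonal_piece, s$dendritic_piece)
  prev <- character(0)
  for (th in c(2, 4, 6, 10)) {
    cur <- keyify(detect_synapses(net, th))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_gt(length(prev), 0)
})

test_that("synapses always run from the pre neuron's axon to the post neuron's dendrites", {
  net <- get_small_network()
  syn <- detect_synapses(net, 6)
  expect_gt(nrow(syn), 0)
  expect_true(all(syn$pre != syn$post))            # no autapses
  pieces <- arborsim:::network_pieces(net)
  expect_true(all(pieces$axonal$neuron[syn$axonal_piece] == syn$pre))
  expect_true(all(pieces$dendritic$neuron[syn$dendritic_piece] == syn$post))
  kind <- pieces$dendritic$kind[syn$dendritic_piece]
  expect_identical(c("basal", "apical")[kind], syn$post_kind)
  expect_true(all(syn$orth_dist < 6))
})

test_that("an empty network produces an empty synapse table", {
  net <- toy_network(list(), list(), matrix(numeric(0), 0, 3))
  net$config <- network_config(n_neurons = 1)
  expect_equal(nrow(detect_synapses(net, 4)), 0L)
})
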