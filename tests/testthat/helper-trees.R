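# Hand-built fixture trees and small reference implementations used as
# independent oracles across the test files.

# Build a neurite_tree from explicit node positions and parent pointers.
make_tree <- function(pos, parent, arbor = "basal") {
  structure(list(pos = as.matrix(pos), parent = as.integer(parent),
                 arbor_type = arbor, tips = NULL),
            class = "neurite_tree")
}

# Y-shaped tree: stem of length `stem` up the z axis, two arms of lengths
# `arms` at +/- 45 degrees, each split into `k` collinear pieces.
y_tree <- function(stem = 10, arms = c(5, 5), k = 1) {
  split_pts <- function(from, to, k) {
    t <- seq(0, 1, length.out = k + 1)[-1]
    outer(t, to - from) + rep(from, each = k)
  }
  pos <- matrix(c(0, 0, 0), 1, 3)
  parent <- 0L
  add_chain <- function(pos, parent, from_idx, to, k) {
    pts <- split_pts(pos[from_idx, ], to, k)
    for (i in seq_len(nrow(pts))) {
      pos <- rbind(pos, pts[i, ])
      parent <- c(parent, if (i == 1) from_idx else nrow(pos) - 1L)
    }
    list(pos = pos, parent = parent)
  }
  r <- add_chain(pos, parent, 1L, c(0, 0, stem), k)
  top <- nrow(r$pos)
  u <- sqrt(0.5)
  r <- add_chain(r$pos, r$parent, top, c(arms[1] * u, 0, stem + arms[1] * u), k)
  r <- add_chain(r$pos, r$parent, top, c(-arms[2] * u, 0, stem + arms[2] * u), k)
  make_tree(r$pos, r$parent)
}

# Straight unbranched tree of total length L along +x, in k pieces.
line_tree <- function(L = 100, k = 4, arbor = "basal") {
  pos <- cbind(seq(0, L, length.out = k + 1), 0, 0)
  make_tree(pos, c(0L, seq_len(k)), arbor)
}

# Naive per-tip simulation of the branching process (counts only): the
# brute-force oracle for the tip-count dynamics, written independently of
# the C++ engine (explicit per-tip Bernoulli draws, no normalization
# shortcuts beyond the model definition).
naive_degree_sim <- function(B_inf, E, S, tau, dt, n_steps) {
  gamma <- 0L
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    n <- length(gamma)
    D <- B_inf * (exp(-t / tau) - exp(-(t + dt) / tau))
    newg <- integer(0)
    keep <- logical(n)
    for (j in seq_len(n)) {
      C <- n / sum(2^(-S * gamma))
      p <- min(1, n^(-E) * C * 2^(-S * gamma[j]) * D)
      if (runif(1) < p) newg <- c(newg, rep(gamma[j] + 1L, 2)) else keep[j] <- TRUE
    }
    gamma <- c(gamma[keep], newg)
  }
  length(gamma)
}

# A tiny network-like object wrapping hand-built trees, good enough for
# detect_synapses(): each "neuron" has an axon and one basal tree.
toy_network <- function(axons, dendrites, soma) {
  n <- length(axons)
  neurons <- lapply(seq_len(n), function(i) {
    list(id = i, axon = axons[[i]], basal = list(dendrites[[i]]),
         apical = make_tree(matrix(soma[i, ], 1, 3), 0L, "apical"))
  })
  structure(list(config = network_config(n_neurons = max(n, 1)),
                 soma = soma, soma_diameter = rep(15, n),
                 neurons = neurons, seed = NULL),
            class = "neuron_network")
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix: the
# independent oracle for mean_shortest_path.
floyd_warshall_mean <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n))
    D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  mean(D[upper.tri(D)])
}

# Direct triangle-counting clustering coefficient (nodes with < 2 neighbours
# contribute 0): the independent oracle for clustering_coefficient.
naive_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- sum(adj[nb, nb, drop = FALSE] > 0) / 2
    cc[i] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}

# The worked 4-node / 4-edge example graph: A-B, B-C, B-D, C-D.
worked_example_graph <- function() {
  igraph::graph_from_edgelist(rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 4)),
                              directed = FALSE)
}

# Reduced-duration growth bundle for cheap network-level tests.
fast_growth_params <- function(days = 3) {
  default_growth_params(
    axon = growth_params("axon", total_time = days * 86400),
    basal = growth_params("basal", total_time = days * 86400),
    apical_stem = growth_params("apical_stem", total_time = days * 86400),
    apical_tuft = growth_params("apical_tuft", total_time = days * 86400),
    apical_oblique = growth_params("apical_oblique", total_time = days * 86400),
    tuft_time = 100000)
}

# Small full-duration network shared by synapse/connectivity tests.
get_small_network <- function() {
  if (is.null(.fixture_small$net))
    .fixture_small$net <- grow_network(network_config(n_neurons = 8),
                                       seed = 4711)
  .fixture_small$net
}
.fixture_small <- new.env(parent = emptyenv())

# Shared full-scale fixture for the acceptance tests: grown once per test
# run, reused across test files.
.fixture_env <- new.env(parent = emptyenv())
get_full_network <- function(seed = 20140116) {
  if (is.null(.fixture_env$net))
    .fixture_env$net <- grow_network(network_config(), seed = seed)
  .fixture_env$net
}
get_full_synapses <- function(threshold = 4) {
  key <- paste0("syn", threshold)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- detect_synapses(get_full_network(), threshold)
  .fixture_env[[key]]
}
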