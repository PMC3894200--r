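# Neuron-level connectivity. A *connection* is an ordered neuron pair
# (pre -> post) sharing at least one synapse; its *strength* is the synapse
# count. Graph-theoretical analysis (shortest paths, clustering, small-world)
# is performed on the undirected simple-graph view.

#' Build the neuron-level connectivity graph
#'
#' @param synapses a `synapse_table` from [detect_synapses()].
#' @param n_neurons number of neurons (nodes); defaults to the value recorded
#'   on the synapse table.
#' @return a directed [igraph::igraph] graph with one vertex per neuron and
#'   one edge per connection, with edge attributes `weight` (synapse count),
#'   `n_basal` and `n_apical` (synapses by postsynaptic dendrite kind).
#' @export
build_graph <- function(synapses, n_neurons = attr(synapses, "n_neurons")) {
  if (is.null(n_neurons))
    n_neurons <- if (nrow(synapses)) max(synapses$pre, synapses$post) else 0L
  if (nrow(synapses) == 0)
    return(igraph::make_empty_graph(n = n_neurons, directed = TRUE))
  key <- paste(synapses$pre, synapses$post)
  agg <- data.frame(
    pre = as.integer(vapply(strsplit(unique(key), " "), `[`, "", 1)),
    post = as.integer(vapply(strsplit(unique(key), " "), `[`, "", 2)))
  kf <- factor(key, levels = unique(key))
  agg$weight <- as.integer(table(kf))
  agg$n_basal <- as.integer(tapply(synapses$post_kind == "basal", kf, sum))
  agg$n_apical <- as.integer(tapply(synapses$post_kind == "apical", kf, sum))
  g <- igraph::graph_from_data_frame(agg, directed = TRUE,
                                     vertices = data.frame(name = seq_len(n_neurons)))
  g
}

# undirected simple-graph view (edge iff >= 1 synapse in either direction)
undirected_view <- function(graph) {
  igraph::as_undirected(graph, mode = "collapse",
                        edge.attr.comb = list(weight = "sum", n_basal = "sum",
                                              n_apical = "sum"))
}

#' Connection probability of a graph
#'
#' Fraction of ordered neuron pairs with a connection (`mode = "directed"`,
#' the convention behind the reported average connection probability), or of
#' unordered pairs connected in at least one direction
#' (`mode = "undirected"`).
#'
#' @param graph a directed connectivity graph from [build_graph()].
#' @param mode `"directed"` or `"undirected"`.
#' @return probability in `[0, 1]`.
#' @export
connection_probability <- function(graph, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(graph)
  if (n < 2) return(NA_real_)
  if (mode == "directed") igraph::ecount(graph) / (n * (n - 1))
  else igraph::ecount(undirected_view(graph)) / (n * (n - 1) / 2)
}

#' Mean connection strength (synapses per connection)
#' @param graph a directed connectivity graph with `weight` edge attribute.
#' @return list with `mean`, `sd` and `n` (number of connections).
#' @export
connection_strength_stats <- function(graph) {
  w <- igraph::E(graph)$weight
  if (is.null(w) || !length(w))
    return(list(mean = NaN, sd = NA_real_, n = 0L))
  list(mean = mean(w), sd = stats::sd(w), n = length(w))
}

#' Connection probability versus intersoma distance
#'
#' Bins all neuron pairs by the Euclidean distance between their somata and
#' reports, per bin, the fraction of pairs that are connected. With
#' `mode = "directed"` ordered pairs are counted (an A-B pair contributes
#' twice, once per direction), matching the convention of
#' [connection_probability()].
#'
#' @param graph a directed connectivity graph.
#' @param soma n x 3 matrix of soma positions.
#' @param bin_width bin width, um (default 20, the minimum soma spacing).
#' @param mode `"directed"` or `"undirected"`.
#' @return data.frame with `from`, `to` (bin edges, um), `n_pairs`,
#'   `n_connected` and `probability`.
#' @export
connection_probability_vs_distance <- function(graph, soma, bin_width = 20,
                                               mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(graph)
  stopifnot(nrow(soma) == n)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((soma[ij[, 1], , drop = FALSE] -
                     soma[ij[, 2], , drop = FALSE])^2))
  adj <- igraph::as_adjacency_matrix(graph, sparse = TRUE) > 0
  if (mode == "directed") {
    conn <- c(adj[ij], adj[ij[, c(2, 1), drop = FALSE]])
    d <- c(d, d)
  } else {
    conn <- adj[ij] | adj[ij[, c(2, 1), drop = FALSE]]
  }
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  bin <- cut(d, breaks, right = FALSE)
  n_pairs <- as.integer(table(bin))
  n_conn <- as.integer(tapply(conn, bin, sum))
  n_conn[is.na(n_conn)] <- 0L
  out <- data.frame(from = breaks[-length(breaks)], to = breaks[-1],
                    n_pairs = n_pairs, n_connected = n_conn,
                    probability = ifelse(n_pairs > 0, n_conn / n_pairs, NA))
  out[out$n_pairs > 0, , drop = FALSE]
}

#' Connection-length distributions by dendrite kind
#'
#' Euclidean intersoma distances of connected neuron pairs, split by the
#' postsynaptic dendrite kind. A connection is classified `basal` when all of
#' its synapses are on basal dendrites, `apical` when all are on the apical
#' dendrite, and `mixed` otherwise (mixed connections belong to neither pure
#' class, so the two kind counts need not add up to the total).
#'
#' @param graph a directed connectivity graph from [build_graph()].
#' @param soma n x 3 soma position matrix.
#' @param bin_width histogram bin width, um.
#' @return list with per-kind summaries (`mean`, `sd`, `n`, `hist`) under
#'   `basal`, `apical`, `mixed`.
#' @export
connection_length_distributions <- function(graph, soma, bin_width = 20) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) == 0)
    return(list(basal = list(mean = NaN, sd = NA, n = 0, hist = NULL),
                apical = list(mean = NaN, sd = NA, n = 0, hist = NULL),
                mixed = list(mean = NaN, sd = NA, n = 0, hist = NULL)))
  d <- sqrt(rowSums((soma[el[, 1], , drop = FALSE] -
                     soma[el[, 2], , drop = FALSE])^2))
  nb <- igraph::E(graph)$n_basal
  na_ <- igraph::E(graph)$n_apical
  kind <- ifelse(nb > 0 & na_ == 0, "basal",
                 ifelse(na_ > 0 & nb == 0, "apical", "mixed"))
  one <- function(k) {
    x <- d[kind == k]
    if (!length(x)) return(list(mean = NaN, sd = NA, n = 0, hist = NULL))
    breaks <- seq(0, max(x) + bin_width, by = bin_width)
    list(mean = mean(x), sd = stats::sd(x), n = length(x),
         hist = graphics::hist(x, breaks = breaks, plot = FALSE))
  }
  list(basal = one("basal"), apical = one("apical"), mixed = one("mixed"))
}

#' Degree distributions by dendrite kind
#'
#' In-, out- and total degree of every neuron, computed on the subgraph of
#' connections that include at least one synapse of the given postsynaptic
#' dendrite kind, plus the overall (`all`) graph.
#'
#' @param graph a directed connectivity graph from [build_graph()].
#' @return a list of data.frames (`all`, `basal`, `apical`), each with
#'   columns `neuron`, `in_degree`, `out_degree`, `degree`.
#' @export
degree_distributions <- function(graph) {
  sub <- function(g) data.frame(
    neuron = seq_len(igraph::vcount(g)),
    in_degree = igraph::degree(g, mode = "in"),
    out_degree = igraph::degree(g, mode = "out"),
    degree = igraph::degree(undirected_view(g), mode = "all"))
  if (igraph::ecount(graph) == 0)
    return(list(all = sub(graph), basal = sub(graph), apical = sub(graph)))
  gb <- igraph::subgraph_from_edges(graph, igraph::E(graph)[igraph::E(graph)$n_basal > 0],
                                    delete.vertices = FALSE)
  ga <- igraph::subgraph_from_edges(graph, igraph::E(graph)[igraph::E(graph)$n_apical > 0],
                                    delete.vertices = FALSE)
  list(all = sub(graph), basal = sub(gb), apical = sub(ga))
}

#' Mean shortest path length of an undirected graph
#'
#' Average of the shortest path lengths over all unordered node pairs. The
#' graph must be connected (the reference network and all its randomized
#' versions are).
#'
#' @param graph an igraph graph; a directed graph is converted to its
#'   undirected view first.
#' @return mean shortest path length.
#' @export
mean_shortest_path <- function(graph) {
  if (igraph::is_directed(graph)) graph <- undirected_view(graph)
  n <- igraph::vcount(graph)
  if (n < 2) stop("graph needs at least two nodes")
  D <- igraph::distances(graph, weights = NA)  # hop counts, not synapse weights
  up <- D[upper.tri(D)]
  if (any(is.infinite(up))) stop("graph is not connected")
  mean(up)
}

#' Average clustering coefficient of an undirected graph
#'
#' Per-node coefficient \eqn{2 n_i / (k_i (k_i - 1))}, where \eqn{n_i} is the
#' number of edges among the neighbours of node \eqn{i} and \eqn{k_i} its
#' number of neighbours; nodes with fewer than two neighbours contribute 0.
#' The network value is the mean over all nodes.
#'
#' @param graph an igraph graph; directed graphs are collapsed first.
#' @return clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(graph) {
  if (igraph::is_directed(graph)) graph <- undirected_view(graph)
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  mean(cc)
}

#' Randomize the edges of a graph
#'
#' Creates a random simple graph with the same number of nodes and edges
#' (full edge redistribution, not degree-preserving rewiring). Draws are
#' repeated until the randomized graph is connected, mirroring the
#' reachability check applied to the reference network.
#'
#' @param graph an undirected igraph graph (directed input is collapsed).
#' @param max_tries redraw budget.
#' @return an undirected igraph graph.
#' @export
randomize_edges <- function(graph, max_tries = 100) {
  if (igraph::is_directed(graph)) graph <- undirected_view(graph)
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  for (k in seq_len(max_tries)) {
    g <- igraph::sample_gnm(n, m, directed = FALSE)
    if (igraph::is_connected(g)) return(g)
  }
  stop("could not draw a connected randomized graph in ", max_tries, " tries")
}

#' Small-world analysis
#'
#' Compares the clustering coefficient and mean shortest path length of the
#' network with those of edge-randomized graphs of equal size:
#' \eqn{\gamma = C_{orig}/C_{rand}}, \eqn{\lambda = L_{orig}/L_{rand}};
#' \eqn{\gamma/\lambda > 1} indicates small-world topology.
#'
#' @param graph connectivity graph (directed graphs are collapsed to the
#'   undirected view).
#' @param n_rand number of independent randomizations to average over.
#' @return an object of class `small_world_report`.
#' @export
small_world_report <- function(graph, n_rand = 3) {
  if (igraph::is_directed(graph)) graph <- undirected_view(graph)
  L <- mean_shortest_path(graph)
  C <- clustering_coefficient(graph)
  Ls <- numeric(n_rand); Cs <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    r <- randomize_edges(graph)
    Ls[i] <- mean_shortest_path(r)
    Cs[i] <- clustering_coefficient(r)
  }
  out <- list(L_orig = L, C_orig = C,
              L_rand = mean(Ls), C_rand = mean(Cs),
              L_rand_runs = Ls, C_rand_runs = Cs,
              gamma = C / mean(Cs), lambda = L / mean(Ls),
              small_worldness = (C / mean(Cs)) / (L / mean(Ls)),
              n_randomizations = n_rand)
  class(out) <- "small_world_report"
  out
}

#' @export
print.small_world_report <- function(x, ...) {
  cat("Small-world analysis\n")
  cat(sprintf("  L = %.3f (random %.3f)   C = %.3f (random %.3f)\n",
              x$L_orig, x$L_rand, x$C_orig, x$C_rand))
  cat(sprintf("  gamma = %.3f  lambda = %.3f  gamma/lambda = %.3f  (%d randomizations)\n",
              x$gamma, x$lambda, x$small_worldness, x$n_randomizations))
  invisible(x)
}

#' Write the connection edge list to TSV
#' @param graph a directed connectivity graph.
#' @param path output file.
#' @export
write_edges <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  df <- data.frame(pre = el[, 1], post = el[, 2],
                   weight = igraph::E(graph)$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
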