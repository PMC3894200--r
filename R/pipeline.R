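# End-to-end pipeline: grow -> detect synapses -> analyze connectivity,
# with all artifacts written to disk and a manifest for exact reproduction.

#' Assemble a run configuration
#'
#' @param network a [network_config()].
#' @param growth parameter bundle from [default_growth_params()].
#' @param threshold synapse distance threshold(s), um.
#' @param n_rand randomizations for the small-world analysis.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(network = network_config(),
                       growth = default_growth_params(),
                       threshold = 4, n_rand = 3, seed = 1) {
  structure(list(network = network, growth = growth, threshold = threshold,
                 n_rand = n_rand, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' The configuration round-trips losslessly: `read_run_config(write_run_config(x))`
#' reproduces every field.
#'
#' @param config a [run_config()].
#' @param path JSON file.
#' @return `write_run_config`: the path; `read_run_config`: a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- list(network = unclass(config$network),
            growth = lapply(config$growth, function(g)
              if (inherits(g, "growth_params")) unclass(g) else g),
            threshold = config$threshold, n_rand = config$n_rand,
            seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  netfields <- setdiff(names(x$network), "n_basal_range")
  net <- do.call(network_config, c(x$network[setdiff(netfields, character(0))],
                                   list(n_basal_range = unlist(x$network$n_basal_range))))
  gp <- list()
  for (nm in c("axon", "basal", "apical_stem", "apical_tuft", "apical_oblique")) {
    g <- x$growth[[nm]]
    if (is.null(g)) stop("config is missing the growth parameter table '", nm, "'")
    g$arbor <- NULL
    gp[[nm]] <- do.call(growth_params, c(list(arbor = nm), g))
  }
  growth <- default_growth_params(
    axon = gp$axon, basal = gp$basal, apical_stem = gp$apical_stem,
    apical_tuft = gp$apical_tuft, apical_oblique = gp$apical_oblique,
    trunk_length_mn = x$growth$trunk_length_mn,
    trunk_length_sd = x$growth$trunk_length_sd,
    tuft_time = x$growth$tuft_time,
    n_oblique_range = unlist(x$growth$n_oblique_range))
  run_config(network = net, growth = growth, threshold = unlist(x$threshold),
             n_rand = x$n_rand, seed = x$seed)
}

#' Run the full pipeline
#'
#' Grows the network, detects synapses at each configured threshold, builds
#' the connectivity graph and computes the connectivity report. Writes, under
#' `out_dir`: per-neuron SWC files (`swc/neuron_<id>.swc`), the network
#' manifest (`network.tsv`), a synapse table per threshold
#' (`synapses_<t>um.tsv`), the edge list (`edges_<t>um.tsv`), morphometry
#' (`morphometry.tsv`), the scalar report (`report.json`) and a reproduction
#' manifest (`manifest.json`, config + seed).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param save_swc also write per-neuron SWC files (default TRUE).
#' @return the report, invisibly: list with `network` summary, per-threshold
#'   synapse/connectivity statistics and the small-world report.
#' @export
run_pipeline <- function(config, out_dir = NULL, save_swc = TRUE) {
  stopifnot(inherits(config, "run_config"))
  net <- grow_network(config$network, config$growth, seed = config$seed)
  report <- list(seed = config$seed, network = unclass(summary(net)))
  morpho <- list(
    axon = population_stats(lapply(net$neurons, `[[`, "axon")),
    basal = population_stats(unlist(lapply(net$neurons, `[[`, "basal"),
                                    recursive = FALSE)),
    apical = population_stats(lapply(net$neurons, `[[`, "apical")))
  thresholds <- config$threshold
  syn_tables <- list(); graphs <- list()
  for (th in thresholds) {
    syn <- detect_synapses(net, threshold = th)
    g <- build_graph(syn)
    stats <- connection_strength_stats(g)
    thr_rep <- list(threshold = th, n_synapses = nrow(syn),
                    n_connections = stats$n,
                    synapses_per_connection = stats$mean,
                    synapses_per_connection_sd = stats$sd,
                    connection_probability = connection_probability(g),
                    mean_post_path_dist = mean(syn$post_path_dist),
                    mean_post_eucl_dist = mean(syn$post_eucl_dist),
                    mean_pre_path_dist = mean(syn$pre_path_dist),
                    mean_pre_eucl_dist = mean(syn$pre_eucl_dist))
    und <- undirected_view(g)
    if (igraph::vcount(g) > 1 && igraph::is_connected(und)) {
      sw <- small_world_report(g, n_rand = config$n_rand)
      thr_rep$small_world <- sw[c("L_orig", "C_orig", "L_rand", "C_rand",
                                  "gamma", "lambda", "small_worldness")]
    }
    report$thresholds[[paste0("um", th)]] <- thr_rep
    syn_tables[[as.character(th)]] <- syn
    graphs[[as.character(th)]] <- g
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- data.frame(
      id = seq_along(net$neurons),
      x = net$soma[, 1], y = net$soma[, 2], z = net$soma[, 3],
      diameter = net$soma_diameter,
      n_basal = vapply(net$neurons, function(n) length(n$basal), 0L))
    utils::write.table(manifest, file.path(out_dir, "network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (save_swc) {
      dir.create(file.path(out_dir, "swc"), showWarnings = FALSE)
      for (i in seq_along(net$neurons))
        write_swc(net$neurons[[i]], file.path(out_dir, sprintf("swc/neuron_%03d.swc", i)),
                  soma_radius = net$soma_diameter[i] / 2)
    }
    mtab <- do.call(rbind, lapply(names(morpho), function(k)
      cbind(arbor = k, morpho[[k]])))
    utils::write.table(mtab, file.path(out_dir, "morphometry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (th in thresholds) {
      write_synapses(syn_tables[[as.character(th)]],
                     file.path(out_dir, sprintf("synapses_%gum.tsv", th)))
      write_edges(graphs[[as.character(th)]],
                  file.path(out_dir, sprintf("edges_%gum.tsv", th)))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    write_run_config(config, file.path(out_dir, "manifest.json"))
  }
  invisible(list(report = report, network = net, synapses = syn_tables,
                 graphs = graphs, morphometry = morpho))
}
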