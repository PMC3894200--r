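#' Network geometry configuration
#'
#' Geometry of the simulated cortical L2/3 patch: a disc-shaped (cylindrical)
#' volume in which somata are placed uniformly at random subject to a minimum
#' spacing. Defaults reproduce the reference setup: 250 pyramidal neurons in
#' a cylinder of radius 93 um and height 360 um with 20 um minimum soma
#' spacing (about 25,000 neurons per mm^3), each with one descending axon,
#' one ascending apical dendrite and 4-8 basal dendrites.
#'
#' @param n_neurons number of neurons.
#' @param disc_radius cylinder radius, um.
#' @param disc_height cylinder height, um.
#' @param min_soma_spacing minimum pairwise soma distance, um.
#' @param soma_diameter_mn,soma_diameter_sd soma diameter distribution, um
#'   (visualization/SWC only; never used for synapse geometry).
#' @param n_basal_range integer interval for the per-neuron basal tree count.
#' @param max_place_attempts rejection-sampling budget for soma placement.
#' @return an object of class `network_config`.
#' @export
network_config <- function(n_neurons = 250, disc_radius = 93,
                           disc_height = 360, min_soma_spacing = 20,
                           soma_diameter_mn = 15, soma_diameter_sd = 1.5,
                           n_basal_range = c(4L, 8L),
                           max_place_attempts = 20000) {
  stopifnot(n_neurons >= 0, disc_radius > 0, disc_height > 0,
            min_soma_spacing > 0, length(n_basal_range) == 2,
            n_basal_range[1] >= 1, n_basal_range[2] <= 12,
            n_basal_range[1] <= n_basal_range[2])
  cfg <- structure(list(
    n_neurons = as.integer(n_neurons), disc_radius = disc_radius,
    disc_height = disc_height, min_soma_spacing = min_soma_spacing,
    soma_diameter_mn = soma_diameter_mn, soma_diameter_sd = soma_diameter_sd,
    n_basal_range = as.integer(n_basal_range),
    max_place_attempts = max_place_attempts), class = "network_config")
  # crude feasibility check: spheres of radius spacing/2 at ~60% packing
  vol <- pi * disc_radius^2 * disc_height
  need <- n_neurons * (4 / 3) * pi * (min_soma_spacing / 2)^3
  if (need > 0.6 * vol)
    stop("volume cannot hold ", n_neurons, " somata at spacing ",
         min_soma_spacing, " um; reduce n_neurons or the spacing")
  cfg
}

#' Expected soma density of a configuration
#' @param config a [network_config()].
#' @return neurons per mm^3.
#' @export
soma_density <- function(config) {
  vol_mm3 <- pi * (config$disc_radius / 1000)^2 * (config$disc_height / 1000)
  config$n_neurons / vol_mm3
}

#' Place somata in the cylindrical volume
#'
#' Uniform rejection sampling: candidate positions are drawn uniformly in the
#' cylinder and accepted if at least `min_soma_spacing` from all accepted
#' somata.
#'
#' @param config a [network_config()].
#' @return an `n x 3` matrix of soma positions (um); the cylinder axis is z,
#'   spanning `[0, disc_height]`, centred on x = y = 0.
#' @export
place_somata <- function(config) {
  stopifnot(inherits(config, "network_config"))
  n <- config$n_neurons
  out <- matrix(numeric(0), 0, 3)
  if (n == 0) return(out)
  r2 <- config$disc_radius^2
  minsq <- config$min_soma_spacing^2
  attempts <- 0
  while (nrow(out) < n) {
    attempts <- attempts + 1
    if (attempts > config$max_place_attempts)
      stop("soma placement failed after ", attempts,
           " attempts; reduce n_neurons or min_soma_spacing")
    x <- stats::runif(1, -config$disc_radius, config$disc_radius)
    y <- stats::runif(1, -config$disc_radius, config$disc_radius)
    if (x * x + y * y > r2) next
    z <- stats::runif(1, 0, config$disc_height)
    if (nrow(out)) {
      d2 <- (out[, 1] - x)^2 + (out[, 2] - y)^2 + (out[, 3] - z)^2
      if (any(d2 < minsq)) next
    }
    out <- rbind(out, c(x, y, z))
  }
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

# random unit vector outside a cone of half-angle `exclude` around +z
# (the apical direction) and its mirror around -z (the axon).
random_basal_direction <- function(exclude = 30 * pi / 180) {
  repeat {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2))
    if (abs(v[3]) < cos(exclude)) return(v)
  }
}

#' Grow a network of neurons
#'
#' Places `config$n_neurons` somata ([place_somata()]) and grows, for each
#' neuron, one axon (initial direction straight down, -z), one composite
#' apical dendrite (straight up, +z; see [grow_apical()]) and a uniform
#' random number of basal dendrites with initial directions sampled
#' uniformly on the sphere excluding cones around the +z/-z axes.
#'
#' When `seed` is given, every neuron is grown on its own deterministic RNG
#' substream derived from the master seed, so the same neuron ids always get
#' the same morphology regardless of how many neurons are grown.
#'
#' @param config a [network_config()].
#' @param params parameter bundle from [default_growth_params()].
#' @param seed optional master seed (integer).
#' @return an object of class `neuron_network`: list with `config`, `soma`
#'   (n x 3 matrix), `soma_diameter`, `neurons` (per neuron: `axon`,
#'   `basal` list, `apical` trees), and `seed`.
#' @examples
#' \donttest{
#' net <- grow_network(network_config(n_neurons = 3), seed = 1)
#' summary(net)
#' }
#' @export
grow_network <- function(config = network_config(),
                         params = default_growth_params(), seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  for (nm in c("axon", "basal", "apical_stem", "apical_tuft", "apical_oblique"))
    if (!inherits(params[[nm]], "growth_params"))
      stop("params$", nm, " must be a growth_params object")
  if (!is.null(seed)) set.seed(substream_seed(seed, 0L))
  soma <- place_somata(config)
  dia <- abs(stats::rnorm(config$n_neurons, config$soma_diameter_mn,
                          config$soma_diameter_sd))
  neurons <- vector("list", config$n_neurons)
  for (i in seq_len(config$n_neurons)) {
    if (!is.null(seed)) set.seed(substream_seed(seed, i))
    n_basal <- sample(seq(config$n_basal_range[1], config$n_basal_range[2]), 1)
    axon <- grow_tree(params$axon, root = soma[i, ], direction = c(0, 0, -1))
    basal <- lapply(seq_len(n_basal), function(k)
      grow_tree(params$basal, root = soma[i, ],
                direction = random_basal_direction()))
    apical <- grow_apical(params, root = soma[i, ], direction = c(0, 0, 1))
    neurons[[i]] <- list(id = i, axon = axon, basal = basal, apical = apical)
  }
  structure(list(config = config, params = params, soma = soma,
                 soma_diameter = dia, neurons = neurons, seed = seed),
            class = "neuron_network")
}

# deterministic per-neuron substream seed below 2^31
substream_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 8191 + 12345) %% 2147483647)
}

#' @export
print.neuron_network <- function(x, ...) {
  cat(sprintf("<neuron_network> %d neurons in cylinder r=%g um, h=%g um\n",
              x$config$n_neurons, x$config$disc_radius, x$config$disc_height))
  invisible(x)
}

#' @export
summary.neuron_network <- function(object, ...) {
  n <- length(object$neurons)
  axl <- vapply(object$neurons, function(nr) tree_total_length(nr$axon), 0)
  bl <- vapply(object$neurons, function(nr)
    sum(vapply(nr$basal, tree_total_length, 0)), 0)
  apl <- vapply(object$neurons, function(nr) tree_total_length(nr$apical), 0)
  nb <- vapply(object$neurons, function(nr) length(nr$basal), 0L)
  out <- list(n_neurons = n, density_mm3 = soma_density(object$config),
              mean_axon_length = mean(axl),
              mean_basal_field_length = mean(bl),
              mean_basal_tree_length = mean(bl / nb),
              mean_apical_length = mean(apl),
              mean_n_basal = mean(nb))
  class(out) <- "summary.neuron_network"
  out
}

#' @export
print.summary.neuron_network <- function(x, ...) {
  cat(sprintf("Network of %d neurons (%.0f per mm^3)\n", x$n_neurons, x$density_mm3))
  cat(sprintf("  mean axonal length:        %8.0f um\n", x$mean_axon_length))
  cat(sprintf("  mean basal tree length:    %8.0f um (field %0.f um, %.1f trees)\n",
              x$mean_basal_tree_length, x$mean_basal_field_length, x$mean_n_basal))
  cat(sprintf("  mean apical length:        %8.0f um\n", x$mean_apical_length))
  invisible(x)
}

#' Plot a neuron network (xz projection)
#'
#' @param x a `neuron_network`.
#' @param neurons indices of neurons to draw (default: all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.neuron_network <- function(x, neurons = seq_along(x$neurons), ...) {
  graphics::plot(NA, xlim = range(x$soma[, 1]) + c(-200, 200),
                 ylim = range(x$soma[, 3]) + c(-400, 300),
                 xlab = "x (um)", ylab = "z (um)", asp = 1, ...)
  draw <- function(tree, col) {
    idx <- which(tree$parent > 0)
    graphics::segments(tree$pos[tree$parent[idx], 1], tree$pos[tree$parent[idx], 3],
                       tree$pos[idx, 1], tree$pos[idx, 3], col = col)
  }
  for (i in neurons) {
    nr <- x$neurons[[i]]
    draw(nr$axon, "darkgreen")
    for (b in nr$basal) draw(b, "firebrick")
    draw(nr$apical, "tomato")
    graphics::points(x$soma[i, 1], x$soma[i, 3], pch = 16, col = "purple")
  }
  invisible(x)
}
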