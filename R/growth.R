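#' Per-tip branching probability
#'
#' Probability that a terminal segment (growth cone) of centrifugal order
#' `gamma` branches during the time bin \eqn{[t, t + \Delta t)}, given the
#' momentary tip population of its tree. See [growth_params()] for the model.
#' The order-normalization coefficient \eqn{C(t)} requires the sum of
#' \eqn{2^{-S\gamma_i}} over all current tips, supplied as
#' `sum_2_pow_minus_S_gamma`; with the default `NULL` the single-tip value
#' \eqn{2^{-S\,\mathrm{gamma}}} is used (valid when `n_tips = 1`).
#'
#' Values are clamped to `[0, 1]`; a clamp triggers a warning since it means
#' the time step is too coarse for the supplied parameters.
#'
#' @param params a [growth_params()] object.
#' @param t bin start time, seconds.
#' @param n_tips number of terminal segments in the tree (>= 1).
#' @param gamma centrifugal order of this tip.
#' @param sum_2_pow_minus_S_gamma sum of `2^(-S*gamma_i)` over all tips.
#' @return branching probability in `[0, 1]` (vectorized over `gamma`).
#' @examples
#' p <- growth_params("basal")
#' branching_probability(p, t = 0, n_tips = 1, gamma = 0)
#' @export
branching_probability <- function(params, t, n_tips, gamma,
                                  sum_2_pow_minus_S_gamma = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (n_tips < 1) stop("n_tips must be >= 1")
  if (any(t < 0)) stop("t must be >= 0")
  if (is.null(sum_2_pow_minus_S_gamma))
    sum_2_pow_minus_S_gamma <- sum(2^(-params$S * gamma))
  D <- params$B_inf * (exp(-t / params$tau) - exp(-(t + params$dt) / params$tau))
  C <- n_tips / sum_2_pow_minus_S_gamma
  p <- n_tips^(-params$E) * C * 2^(-params$S * gamma) * D
  if (any(p > 1)) {
    warning("branching probability exceeded 1 and was clamped; ",
            "parameters are too aggressive for this time step")
    p <- pmin(p, 1)
  }
  pmax(p, 0)
}

#' Draw an initial elongation rate
#'
#' Samples the fixed elongation rate assigned to a new growth cone:
#' a Gaussian with mean `eri_mn` and SD `eri_sd`, truncated at zero by
#' resampling (retraction is not modelled, so rates are non-negative).
#'
#' @param params a [growth_params()] object.
#' @param n number of independent draws.
#' @return vector of elongation rates, um/s.
#' @export
initialize_elongation_rate <- function(params, n = 1) {
  stopifnot(inherits(params, "growth_params"))
  if (params$eri_sd <= 0) return(rep(params$eri_mn, n))
  r <- stats::rnorm(n, params$eri_mn, params$eri_sd)
  while (any(neg <- r < 0))
    r[neg] <- stats::rnorm(sum(neg), params$eri_mn, params$eri_sd)
  r
}

new_neurite_tree <- function(pos, parent, arbor_type, tips = NULL) {
  structure(list(pos = pos, parent = as.integer(parent),
                 arbor_type = arbor_type, tips = tips),
            class = "neurite_tree")
}

#' Grow a single neurite tree
#'
#' Runs the stochastic outgrowth model for one arborization: at every time
#' step each growth cone elongates by `rate * dt` along its direction (with a
#' direction perturbation every `turn_step_length` of grown length), then
#' branches with the Van Pelt branching probability, splitting into two
#' daughter cones with symmetric directions and freshly drawn elongation
#' rates. The result is a rooted tree of piecewise-linear elements no longer
#' than `turn_step_length` (plus one step's advance).
#'
#' @param params a [growth_params()] object.
#' @param root numeric length-3 root position, um.
#' @param direction initial outgrowth direction (normalized internally).
#' @param total_time override of `params$total_time`, seconds.
#' @return a `neurite_tree`: list with `pos` (N x 3 node matrix), `parent`
#'   (1-based parent index per node, 0 for the root), `arbor_type`, `tips`
#'   (node indices of terminal tips). Node order satisfies `parent < node`.
#' @examples
#' set.seed(1)
#' tr <- grow_tree(growth_params("basal", total_time = 2 * 86400))
#' tree_degree(tr)
#' @export
grow_tree <- function(params, root = c(0, 0, 0), direction = c(0, 0, 1),
                      total_time = NULL) {
  stopifnot(inherits(params, "growth_params"), length(root) == 3,
            length(direction) == 3)
  if (sum(direction^2) == 0) stop("initial direction must be non-zero")
  tt <- if (is.null(total_time)) params$total_time else total_time
  res <- .grow_tree_cpp(as.numeric(root), as.numeric(direction),
                        params$B_inf, params$E, params$S, params$tau,
                        params$eri_mn, params$eri_sd,
                        params$dt, tt,
                        params$turn_step_length, params$turn_angle_sd,
                        params$branch_angle_mean, params$branch_angle_sd,
                        as.integer(params$tip_cap))
  new_neurite_tree(res$pos, res$parent,
                   arbor_type = params$arbor, tips = res$tips)
}

# Unbranched trunk polyline: pieces of at most turn_step_length with the same
# turning model as grow_tree. Returns node positions plus the elapsed growth
# time at each node (used to start oblique/tuft clocks).
grow_trunk <- function(length_target, rate, root, direction,
                       turn_step = 5, turn_sd = 8 * pi / 180) {
  dir <- direction / sqrt(sum(direction^2))
  n_full <- floor(length_target / turn_step)
  lens <- c(rep(turn_step, n_full), length_target - n_full * turn_step)
  lens <- lens[lens > 1e-9]
  pos <- matrix(0, nrow = length(lens) + 1, ncol = 3)
  pos[1, ] <- root
  for (i in seq_along(lens)) {
    pos[i + 1, ] <- pos[i, ] + lens[i] * dir
    dir <- dir + turn_sd * stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
  }
  list(pos = pos, parent = c(0L, seq_len(length(lens))),
       cum_len = c(0, cumsum(lens)),
       cum_time = c(0, cumsum(lens)) / rate, final_dir = dir)
}

# Graft `sub` (a neurite_tree) onto `tree` so that sub's root coincides with
# node `at` of tree. Node order keeps parents before children.
graft_tree <- function(tree, sub, at) {
  offset <- nrow(tree$pos) - 1L
  nsub <- nrow(sub$pos)
  map <- c(at, seq_len(nsub - 1L) + offset + 1L)
  pos <- rbind(tree$pos, sub$pos[-1L, , drop = FALSE])
  parent <- c(tree$parent, map[sub$parent[-1L]])
  new_neurite_tree(pos, parent, tree$arbor_type)
}

#' Grow a composite apical dendrite
#'
#' Builds the apical arbor of a pyramidal neuron from its three
#' sub-compartments, each with its own parameter set: an unbranched main stem
#' (trunk) of drawn length `Normal(trunk_length_mn, trunk_length_sd)` um grown
#' at the stem elongation rate, an apical tuft grown from the distal end of
#' the trunk for `tuft_time` seconds, and `n_oblique_range` oblique subtrees
#' attached at uniform positions along the trunk. Each sub-unit runs on a
#' local developmental clock that starts when the trunk reaches its root
#' (trunk growth consumes `length/rate` seconds of the total).
#'
#' @param params a parameter bundle as returned by [default_growth_params()]
#'   (components `apical_stem`, `apical_tuft`, `apical_oblique`,
#'   `trunk_length_mn`, `trunk_length_sd`, `tuft_time`, `n_oblique_range`).
#' @param root,direction root position and initial direction (pia-ward, +z).
#' @return a `neurite_tree` with `arbor_type = "apical"`.
#' @export
grow_apical <- function(params, root = c(0, 0, 0), direction = c(0, 0, 1)) {
  stem <- params$apical_stem
  total <- stem$total_time
  rate <- initialize_elongation_rate(stem)
  repeat {
    L <- stats::rnorm(1, params$trunk_length_mn, params$trunk_length_sd)
    if (L > 0) break
  }
  L <- min(L, rate * total)
  tr <- grow_trunk(L, rate, root, direction,
                   turn_step = stem$turn_step_length,
                   turn_sd = stem$turn_angle_sd)
  tree <- new_neurite_tree(tr$pos, tr$parent, "apical")
  t_trunk <- tr$cum_time[length(tr$cum_time)]

  # oblique side branches along the trunk
  n_obl <- sample(seq(params$n_oblique_range[1], params$n_oblique_range[2]), 1)
  if (n_obl > 0 && nrow(tr$pos) > 1) {
    at_len <- stats::runif(n_obl, 0, L)
    for (a in at_len) {
      node <- which.min(abs(tr$cum_len - a))
      t_rem <- total - tr$cum_time[node]
      if (t_rem <= 0) next
      axis <- direction / sqrt(sum(direction^2))
      repeat { # random direction well away from the trunk axis
        d <- stats::rnorm(3)
        d <- d / sqrt(sum(d^2))
        if (abs(sum(d * axis)) < 0.8) break
      }
      sub <- grow_tree(params$apical_oblique, root = tr$pos[node, ],
                       direction = d, total_time = t_rem)
      tree <- graft_tree(tree, sub, at = node)
    }
  }

  # apical tuft from the distal end of the trunk
  t_tuft <- min(params$tuft_time, total - t_trunk)
  if (t_tuft > 0) {
    tuft <- grow_tree(params$apical_tuft, root = tr$pos[nrow(tr$pos), ],
                      direction = tr$final_dir, total_time = t_tuft)
    tree <- graft_tree(tree, tuft, at = nrow(tr$pos))
  }
  tree
}

#' @export
print.neurite_tree <- function(x, ...) {
  cat(sprintf("<neurite_tree: %s> %d nodes, degree %d, total length %.1f um\n",
              x$arbor_type, nrow(x$pos), tree_degree(x), tree_total_length(x)))
  invisible(x)
}

# piece lengths (one per node; 0 for the root)
piece_lengths <- function(tree) {
  p <- tree$parent
  len <- numeric(nrow(tree$pos))
  idx <- which(p > 0)
  d <- tree$pos[idx, , drop = FALSE] - tree$pos[p[idx], , drop = FALSE]
  len[idx] <- sqrt(rowSums(d^2))
  len
}

# cumulative path length from the root, per node
cum_path <- function(tree) .cum_path_cpp(tree$pos, tree$parent)

# number of children per node
child_count <- function(tree) {
  tabulate(tree$parent[tree$parent > 0], nbins = nrow(tree$pos))
}

#' Total length of a tree
#' @param tree a `neurite_tree`.
#' @return sum of all line-piece lengths, um.
#' @export
tree_total_length <- function(tree) sum(piece_lengths(tree))
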