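# Genetic-algorithm fitting of the outgrowth parameters to target
# morphometric statistics (means and SDs of the six shape characteristics;
# 12 measures in total).

#' Morphometric fitness of a candidate parameter set
#'
#' Sum of relative absolute deviations between target and simulated values,
#' \eqn{\sum_i |t_i - \nu_i| / t_i}, over the supplied measures (smaller is
#' better; 0 means a perfect match). Targets that are zero or missing are
#' skipped, since the relative error is undefined there.
#'
#' @param target,simulated numeric vectors of matching length (or data.frames
#'   from [population_stats()], matched on `characteristic`).
#' @param weights optional per-measure weights (default 1).
#' @return non-negative fitness score.
#' @examples
#' morphometric_fitness(c(10, 2), c(11, 2))  # 0.1
#' @export
morphometric_fitness <- function(target, simulated, weights = NULL) {
  if (is.data.frame(target)) {
    tv <- c(target$mean, target$sd)
    sv <- c(simulated$mean[match(target$characteristic, simulated$characteristic)],
            simulated$sd[match(target$characteristic, simulated$characteristic)])
  } else {
    tv <- as.numeric(target)
    sv <- as.numeric(simulated)
  }
  stopifnot(length(tv) == length(sv))
  if (is.null(weights)) weights <- rep(1, length(tv))
  ok <- is.finite(tv) & is.finite(sv) & tv > 0
  if (!any(ok)) return(Inf)
  sum(weights[ok] * abs(tv[ok] - sv[ok]) / tv[ok])
}

# the six genes under optimization, with their search bounds; positive
# scale-like genes spanning several decades are searched on a log10 scale
ga_genes <- function() {
  list(B_inf = c(0.1, 30), E = c(0, 1), S = c(-1, 1.5),
       tau = c(5e4, 3e6), eri_mn = c(1e-5, 2e-3), eri_sd = c(1e-7, 1e-3))
}

ga_log_genes <- function() c("B_inf", "tau", "eri_mn", "eri_sd")

ga_simulate_stats <- function(genes, base_params, n_trees) {
  p <- base_params
  for (nm in names(genes)) p[[nm]] <- genes[[nm]]
  p <- validate_growth_params(p)
  trees <- lapply(seq_len(n_trees), function(i) grow_tree(p))
  population_stats(trees)
}

#' Fit growth parameters with a genetic algorithm
#'
#' Evolves candidate parameter sets (`B_inf`, `E`, `S`, `tau`, `eri_mn`,
#' `eri_sd`) towards target shape statistics: rank-based selection, uniform
#' crossover, per-gene Gaussian mutation and elitism (the best
#' `n_elite` candidates survive unchanged, so the best fitness is
#' non-increasing across generations). Each candidate is scored by growing a
#' reduced population of trees and evaluating [morphometric_fitness()]
#' against the targets; candidates whose simulation fails or produces
#' non-finite statistics receive the worst fitness.
#'
#' @param target_stats data.frame from [population_stats()] (columns
#'   `characteristic`, `mean`, `sd`) holding the 12 target measures.
#' @param base_params a [growth_params()] object supplying everything not
#'   under optimization (time step, duration, turning model).
#' @param population,generations GA size controls.
#' @param n_trees trees grown per fitness evaluation.
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_sd initial mutation SD as a fraction of each gene's search
#'   range; annealed linearly to a quarter of this by the last generation.
#' @param n_elite elite count.
#' @param final_reeval_top re-score this many of the best candidates with
#'   `final_reeval_factor * n_trees` trees before declaring the winner
#'   (counters the winner's curse of noisy per-candidate fitness; set to 0 to
#'   disable).
#' @param final_reeval_factor multiplier for the final re-evaluation.
#' @param gene_bounds named list of `c(lower, upper)` search bounds per gene
#'   (defaults cover the full plausible range for 18-day cortical arbors).
#'   Note that `tau` is only identifiable up to a few multiples of the
#'   simulated duration -- beyond that the baseline decays ~linearly and only
#'   `B_inf/tau` matters -- so shorter fitting problems warrant a tighter
#'   `tau` interval.
#' @param seed optional RNG seed.
#' @return object of class `ga_fit`: `params` (best-of-run
#'   [growth_params()]), `fitness`, `history` (best fitness per generation),
#'   `population` (final gene matrix).
#' @export
fit_growth_params <- function(target_stats, base_params = growth_params("basal"),
                              population = 24, generations = 40, n_trees = 30,
                              mutation_rate = 0.25, mutation_sd = 0.1,
                              n_elite = 2, final_reeval_top = 5,
                              final_reeval_factor = 4, gene_bounds = ga_genes(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- gene_bounds
  stopifnot(setequal(names(genes), names(ga_genes())))
  ng <- length(genes)
  is_log <- names(genes) %in% ga_log_genes()
  enc <- function(v) { v[is_log] <- log10(v[is_log]); v }  # genome <-> params
  dec <- function(v) { v[is_log] <- 10^v[is_log]; v }
  lo <- enc(vapply(genes, `[`, 0, 1)); hi <- enc(vapply(genes, `[`, 0, 2))
  pop <- sapply(seq_len(ng), function(j) stats::runif(population, lo[j], hi[j]))
  colnames(pop) <- names(genes)
  # Common random numbers: every candidate is scored on the same RNG stream,
  # so fitness differences reflect the parameters rather than simulation
  # luck. The GA's own stream is saved and restored around evaluations.
  eval_seed <- sample.int(2^30, 1)
  score_one <- function(v, trees = n_trees, sd_offset = 0L) {
    ga_stream <- get(".Random.seed", envir = globalenv())
    set.seed(eval_seed + sd_offset)
    st <- tryCatch(ga_simulate_stats(as.list(dec(v)), base_params, trees),
                   error = function(e) NULL)
    assign(".Random.seed", ga_stream, envir = globalenv())
    if (is.null(st)) return(Inf)
    f <- morphometric_fitness(target_stats, st)
    if (!is.finite(f)) Inf else f
  }
  history <- numeric(generations)
  fit <- apply(pop, 1, score_one)
  for (gen in seq_len(generations)) {
    ord <- order(fit)
    pop <- pop[ord, , drop = FALSE]; fit <- fit[ord]
    history[gen] <- fit[1]
    # rank-based selection weights
    w <- rev(seq_len(population))
    newpop <- pop
    for (k in seq(n_elite + 1, population)) {
      pa <- pop[sample(population, 1, prob = w), ]
      pb <- pop[sample(population, 1, prob = w), ]
      child <- ifelse(stats::runif(ng) < 0.5, pa, pb)   # uniform crossover
      mut <- stats::runif(ng) < mutation_rate
      anneal <- 1 - 0.75 * (gen - 1) / max(generations - 1, 1)
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, anneal * mutation_sd * (hi - lo)[mut])
      newpop[k, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- newpop
    fit <- c(fit[seq_len(n_elite)],
             apply(pop[-seq_len(n_elite), , drop = FALSE], 1, score_one))
  }
  ord <- order(fit)
  if (final_reeval_top > 1) {
    # re-score the front-runners on a fresh, larger simulation so the winner
    # is not an artifact of the shared evaluation stream
    top <- ord[seq_len(min(final_reeval_top, population))]
    refit <- vapply(top, function(i)
      score_one(pop[i, ], trees = n_trees * final_reeval_factor,
                sd_offset = 1L), 0)
    ord <- c(top[order(refit)], setdiff(ord, top))
    fit[ord[1]] <- min(refit)
  }
  best <- as.list(dec(pop[ord[1], ]))
  params <- base_params
  for (nm in names(best)) params[[nm]] <- best[[nm]]
  pop_out <- t(apply(pop[ord, , drop = FALSE], 1, dec))
  colnames(pop_out) <- names(genes)
  structure(list(params = validate_growth_params(params), fitness = fit[ord[1]],
                 history = history, population = pop_out),
            class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("<ga_fit> best fitness %.4f after %d generations\n",
              x$fitness, length(x$history)))
  print(x$params)
  invisible(x)
}
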