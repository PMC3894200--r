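#' Growth parameters for one arbor type
#'
#' Bundles the stochastic outgrowth constants of the Van Pelt-type branching
#' and elongation model for a single arbor type, together with the numerical
#' and geometric knobs of the simulator. Defaults are the optimized values for
#' rat cortical L2/3 pyramidal neurons (per arbor type), a 200 s time step and
#' an 18-day developmental period.
#'
#' The branching model: a terminal segment \eqn{j} of a tree with \eqn{n(t)}
#' tips branches during \eqn{[t, t+\Delta t)} with probability
#' \deqn{p_j(t) = n(t)^{-E} \, C(t) \, 2^{-S\gamma_j} \, B_\infty
#'   \left[e^{-t/\tau} - e^{-(t+\Delta t)/\tau}\right],\quad
#'   C(t) = n(t) / \sum_i 2^{-S\gamma_i},}
#' where \eqn{\gamma_j} is the centrifugal order of the tip, \eqn{E} modulates
#' competition between tips, \eqn{S} the order dependence, \eqn{\tau} the decay
#' of the baseline branching rate, and \eqn{B_\infty} the asymptotic expected
#' number of branching events at a tip for \eqn{E = 0}.
#'
#' Elongation: every new growth cone draws a fixed rate from a Gaussian with
#' mean `eri_mn` and SD `eri_sd` (\eqn{\mu m/s}), truncated at zero by
#' resampling, and keeps it until it branches.
#'
#' @param arbor one of `"axon"`, `"basal"`, `"apical_stem"`, `"apical_tuft"`,
#'   `"apical_oblique"`; selects the default parameter column.
#' @param ... named overrides for any of the fields listed below.
#'
#' @section Fields:
#' * `B_inf`, `E`, `S`, `tau` — branching-model constants (`tau` in seconds).
#' * `eri_mn`, `eri_sd` — elongation-rate initialization, um/s.
#' * `dt` — time step, seconds (default 200).
#' * `total_time` — simulated development, seconds (default 18 days).
#' * `turn_step_length` — grown length between direction evaluations, um
#'   (default 5; this also caps the line-piece length).
#' * `turn_angle_sd` — SD (radians) of the isotropic Gaussian perturbation
#'   applied to the direction at each evaluation (default 8 degrees).
#' * `branch_angle_mean`, `branch_angle_sd` — inter-daughter angle
#'   distribution at branch events, radians (default mean 72, SD 20 degrees).
#' * `tip_cap` — abort threshold for runaway tip counts.
#'
#' @return an object of class `growth_params` (a validated named list).
#' @examples
#' p <- growth_params("axon")
#' p$B_inf
#' growth_params("basal", total_time = 86400)$total_time
#' @export
growth_params <- function(arbor = c("axon", "basal", "apical_stem",
                                    "apical_tuft", "apical_oblique"), ...) {
  arbor <- match.arg(arbor)
  defaults <- list(
    axon           = list(B_inf = 13.2, E = 0.319, S = -0.205, tau = 1681541,
                          eri_mn = 0.000214,  eri_sd = 0.000398),
    basal          = list(B_inf = 2.52, E = 0.73,  S = 0.5,    tau = 259680,
                          eri_mn = 0.0000914, eri_sd = 0.0000366),
    apical_stem    = list(B_inf = 0.1,  E = 0,     S = 0,      tau = 400000,
                          eri_mn = 0.00102,   eri_sd = 0.000026),
    apical_tuft    = list(B_inf = 25,   E = 0.3,   S = 1,      tau = 400000,
                          eri_mn = 0.000225,  eri_sd = 0.000004),
    apical_oblique = list(B_inf = 1.5,  E = 0.3,   S = 1,      tau = 500000,
                          eri_mn = 0.00004,   eri_sd = 0.000001)
  )
  p <- c(defaults[[arbor]], list(
    dt = 200, total_time = 18 * 86400,
    turn_step_length = 5, turn_angle_sd = 8 * pi / 180,
    branch_angle_mean = 72 * pi / 180, branch_angle_sd = 20 * pi / 180,
    tip_cap = 50000, arbor = arbor))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown growth parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  validate_growth_params(structure(p, class = "growth_params"))
}

validate_growth_params <- function(p) {
  stopifnot(
    p$B_inf >= 0, p$tau > 0, p$dt > 0, p$total_time > 0,
    p$eri_mn >= 0, p$eri_sd >= 0,
    p$turn_step_length > 0, p$tip_cap >= 1
  )
  p
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth parameters [", x$arbor, "]\n", sep = "")
  cat(sprintf("  B_inf=%g  E=%g  S=%g  tau=%g s\n", x$B_inf, x$E, x$S, x$tau))
  cat(sprintf("  eri: mean %g, sd %g um/s (truncated normal)\n", x$eri_mn, x$eri_sd))
  cat(sprintf("  dt=%g s, total %g days; turn every %g um (sd %.1f deg)\n",
              x$dt, x$total_time / 86400, x$turn_step_length,
              x$turn_angle_sd * 180 / pi))
  invisible(x)
}

#' Default growth-parameter tables for all five arbor types
#'
#' @param ... per-type overrides, e.g. `axon = growth_params("axon", E = 0.3)`.
#' @return a named list with components `axon`, `basal`, `apical_stem`,
#'   `apical_tuft`, `apical_oblique`, each a [growth_params()] object, plus
#'   `trunk_length_mn = 80`, `trunk_length_sd = 2` (um) and
#'   `tuft_time = 220000` (s), the apical-trunk and tuft-duration settings.
#' @details `tuft_time` is the growth duration of the apical tuft. Running the
#'   tuft parameter column for the full 18 days leads to runaway branching
#'   (see the methods vignette); the default was calibrated once so the mean
#'   total apical length matches the 2456 um reported for L2/3 pyramidal
#'   neurons.
#' @export
default_growth_params <- function(...) {
  out <- list(
    axon = growth_params("axon"),
    basal = growth_params("basal"),
    apical_stem = growth_params("apical_stem"),
    apical_tuft = growth_params("apical_tuft"),
    apical_oblique = growth_params("apical_oblique"),
    trunk_length_mn = 80, trunk_length_sd = 2,
    tuft_time = 220000, n_oblique_range = c(2L, 5L)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(out))
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "))
  out[names(over)] <- over
  out
}
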