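test_that("branching probability matches the closed form in degenerate settings", {
  p <- growth_params("basal", B_inf = 2.52, E = 0, S = 0, tau = 259680, dt = 200)
  # single tip, order zero, t = 0: all modulating terms are 1
  expect_equal(branching_probability(p, t = 0, n_tips = 1, gamma = 0),
               2.52 * (1 - exp(-200 / 259680)))
  # S = 0 removes the order dependency exactly, for any gamma
  for (g in c(0, 3, 7))
    expect_equal(branching_probability(p, t = 1000, n_tips = 5, gamma = g,
                                       sum_2_pow_minus_S_gamma = 5),
                 5 * (1 / 5) * 2.52 * (exp(-1000 / 259680) - exp(-1200 / 259680)))
})

test_that("order-dependency normalization: mean over tips of C * 2^(-S*gamma) is 1", {
  set.seed(11)
  for (S in c(-0.5, -0.205, 0, 0.5, 1)) {
    for (rep in 1:20) {
      gams <- sample(0:9, sample(1:40, 1), replace = TRUE)
      w <- 2^(-S * gams)
      C <- length(gams) / sum(w)
      expect_equal(mean(C * w), 1, tolerance = 1e-9)
    }
  }
})

test_that("cumulative baseline branching events telescope to B_inf for E = S = 0", {
  p <- growth_params("basal", B_inf = 3.1, tau = 5e5, dt = 200)
  t <- seq(0, 5e7, by = 200)
  bins <- p$B_inf * (exp(-t / p$tau) - exp(-(t + p$dt) / p$tau))
  expect_equal(sum(bins), p$B_inf * (1 - exp(-(max(t) + 200) / p$tau)),
               tolerance = 1e-9)
  expect_equal(sum(bins), p$B_inf, tolerance = 1e-3)
})

test_that("branching probability rejects invalid input and clamps at 1", {
  p <- growth_params("basal")
  expect_error(branching_probability(p, t = 0, n_tips = 0, gamma = 0), "n_tips")
  expect_error(growth_params("basal", tau = -1))
  expect_warning(
    pr <- branching_probability(growth_params("basal", B_inf = 1e5, tau = 10),
                                t = 0, n_tips = 1, gamma = 0),
    "clamp")
  expect_equal(pr, 1)
})

test_that("elongation rates follow the zero-truncated Gaussian", {
  p <- growth_params("axon") # eri_mn = 0.000214, eri_sd = 0.000398: heavy truncation
  expect_equal(initialize_elongation_rate(growth_params("basal", eri_sd = 0), 5),
               rep(growth_params("basal")$eri_mn, 5))
  set.seed(99)
  r <- initialize_elongation_rate(p, 1e5)
  expect_true(all(r >= 0))
  # oracle: truncated-normal moments by numerical integration (finite upper
  # limit well past the mass; integrate() cannot resolve the narrow spike on
  # an infinite domain)
  hi <- p$eri_mn + 12 * p$eri_sd
  f0 <- integrate(function(x) dnorm(x, p$eri_mn, p$eri_sd), 0, hi)$value
  m1 <- integrate(function(x) x * dnorm(x, p$eri_mn, p$eri_sd), 0, hi)$value / f0
  m2 <- integrate(function(x) x^2 * dnorm(x, p$eri_mn, p$eri_sd), 0, hi)$value / f0
  s1 <- sqrt(m2 - m1^2)
  expect_lt(abs(mean(r) - m1), 4 * s1 / sqrt(1e5))
  expect_equal(sd(r), s1, tolerance = 0.02)
})

test_that("B_inf = 0 grows a single unbranched neurite of length rate * time", {
  p <- growth_params("basal", B_inf = 0, eri_sd = 0, total_time = 86400)
  set.seed(3)
  tr <- grow_tree(p)
  expect_equal(tree_degree(tr), 1L)
  steps <- floor(p$total_time / p$dt)
  expect_equal(tree_total_length(tr), p$eri_mn * steps * p$dt, tolerance = 1e-9)
  sl <- segment_and_path_lengths(tr)
  expect_length(sl$intermediate, 0)
  expect_equal(sl$path, tree_total_length(tr))
  # pieces never exceed the turn step by more than one advance
  expect_true(all(arborsim:::piece_lengths(tr) <=
                    p$turn_step_length + p$eri_mn * p$dt + 1e-12))
})

test_that("zero growth time yields a degenerate single-piece tree", {
  p <- growth_params("basal", total_time = 100, dt = 200) # zero full steps
  set.seed(4)
  tr <- grow_tree(p)
  expect_equal(nrow(tr$pos), 2L)
  expect_equal(tree_total_length(tr), 0)
})

test_that("growth is bit-reproducible under a fixed seed", {
  p <- growth_params("basal", total_time = 2 * 86400)
  set.seed(123); a <- grow_tree(p)
  set.seed(123); b <- grow_tree(p)
  expect_identical(a, b)
  set.seed(124); c <- grow_tree(p)
  expect_false(identical(a$pos, c$pos))
})

test_that("tip bookkeeping: degree equals 1 + number of branch points", {
  set.seed(7)
  for (i in 1:5) {
    tr <- grow_tree(growth_params("basal", total_time = 6 * 86400))
    kids <- arborsim:::child_count(tr)
    expect_equal(tree_degree(tr), 1L + sum(kids == 2L))
    expect_true(all(kids <= 2L)) # strictly binary branching
  }
})

test_that("runaway growth aborts with a diagnostic", {
  p <- growth_params("apical_tuft", tip_cap = 50, total_time = 10 * 86400)
  set.seed(5)
  expect_error(grow_tree(p), "cap")
})

test_that("tip-count dynamics match the naive per-tip Bernoulli oracle", {
  # E = 0, S = 0 and a small B_inf over 200 steps: compare the mean/SD of the
  # final degree against the explicitly enumerated per-tip simulation
  B <- 2; tau <- 2e4; dt <- 200; n_steps <- 200
  set.seed(31)
  oracle <- replicate(600, naive_degree_sim(B, 0, 0, tau, dt, n_steps))
  p <- growth_params("basal", B_inf = B, E = 0, S = 0, tau = tau, dt = dt,
                     total_time = n_steps * dt, eri_mn = 1e-4, eri_sd = 0)
  set.seed(32)
  mine <- replicate(600, tree_degree(grow_tree(p)))
  se <- sqrt(var(oracle) / 600 + var(mine) / 600)
  expect_lt(abs(mean(oracle) - mean(mine)), 3 * se)
  expect_lt(abs(sd(oracle) - sd(mine)) / sd(oracle), 0.25)
})

test_that("apical composite: trunk length and degenerate cases behave", {
  # trunk only (no tuft, no obliques), zero trunk-length SD: exactly 80 um
  gp <- default_growth_params(trunk_length_sd = 0, tuft_time = 0,
                              n_oblique_range = c(0L, 0L))
  set.seed(41)
  ap <- grow_apical(gp)
  expect_equal(tree_degree(ap), 1L)
  expect_equal(tree_total_length(ap), 80, tolerance = 1e-9)
  # full composite: one valid tree, strictly more material than the trunk
  set.seed(42)
  ap2 <- grow_apical(default_growth_params(trunk_length_sd = 0))
  expect_gt(tree_total_length(ap2), 80)
  expect_gt(tree_degree(ap2), 1L)
  expect_identical(ap2$arbor_type, "apical")
  expect_equal(sum(ap2$parent == 0L), 1L)                  # single root
  expect_true(all(ap2$parent < seq_len(nrow(ap2$pos))))    # acyclic, ordered
  # near-zero growth time: apical reduces to the (truncated) bare trunk
  gp0 <- default_growth_params(
    apical_stem = growth_params("apical_stem", total_time = 200),
    tuft_time = 0, n_oblique_range = c(0L, 0L))
  set.seed(43)
  ap0 <- grow_apical(gp0)
  expect_equal(tree_degree(ap0), 1L)
  expect_lte(tree_total_length(ap0), 0.0011 * 200 + 1e-6)
})
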