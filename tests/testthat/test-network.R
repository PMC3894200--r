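test_that("soma placement respects the spacing and containment constraints", {
  set.seed(51)
  for (rep in 1:5) {
    cfg <- network_config(n_neurons = 40)
    pts <- place_somata(cfg)
    expect_equal(nrow(pts), 40)
    expect_true(all(pts[, 1]^2 + pts[, 2]^2 <= cfg$disc_radius^2))
    expect_true(all(pts[, 3] >= 0 & pts[, 3] <= cfg$disc_height))
    d <- as.matrix(dist(pts))
    expect_true(all(d[upper.tri(d)] >= cfg$min_soma_spacing))
  }
  expect_equal(nrow(place_somata(network_config(n_neurons = 0))), 0L)
  set.seed(52)
  two <- place_somata(network_config(n_neurons = 2))
  expect_gte(dist(two)[1], 20)
})

test_that("the default configuration yields about 25,000 neurons per mm^3", {
  expect_equal(soma_density(network_config()),
               250 / (pi * 0.093^2 * 0.36), tolerance = 1e-12)
  expect_equal(soma_density(network_config()), 25000, tolerance = 0.05)
})

test_that("an infeasible placement fails with advice", {
  expect_error(network_config(n_neurons = 10000, min_soma_spacing = 20),
               "reduce")
  cfg <- network_config(n_neurons = 50, disc_radius = 40, disc_height = 60,
                        min_soma_spacing = 18, max_place_attempts = 2000)
  set.seed(53)
  expect_error(place_somata(cfg), "placement failed")
})

test_that("grown networks satisfy the structural invariants", {
  gp <- fast_growth_params()
  set.seed(54)
  net <- grow_network(network_config(n_neurons = 5), gp)
  expect_length(net$neurons, 5)
  for (nr in net$neurons) {
    expect_identical(nr$axon$arbor_type, "axon")
    expect_gte(length(nr$basal), 4)
    expect_lte(length(nr$basal), 8)
    # axon initially points down, apical up
    expect_lt(nr$axon$pos[2, 3] - nr$axon$pos[1, 3], 0)
    expect_gt(nr$apical$pos[2, 3] - nr$apical$pos[1, 3], 0)
    # every tree is rooted at the soma
    expect_equal(unname(nr$axon$pos[1, ]), unname(net$soma[nr$id, ]))
    for (b in nr$basal)
      expect_equal(unname(b$pos[1, ]), unname(net$soma[nr$id, ]))
  }
})

test_that("a master seed makes the network reproducible and substream-stable", {
  gp <- fast_growth_params()
  a <- grow_network(network_config(n_neurons = 4), gp, seed = 7)
  b <- grow_network(network_config(n_neurons = 4), gp, seed = 7)
  expect_identical(a$soma, b$soma)
  expect_identical(a$neurons, b$neurons)
  c <- grow_network(network_config(n_neurons = 4), gp, seed = 8)
  expect_false(identical(a$neurons, c$neurons))
})

test_that("basal-field length scales with the per-tree length", {
  gp <- fast_growth_params()
  set.seed(55)
  net <- grow_network(network_config(n_neurons = 6), gp)
  s <- summary(net)
  expect_equal(s$mean_basal_field_length,
               s$mean_basal_tree_length * s$mean_n_basal, tolerance = 0.3)
})
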