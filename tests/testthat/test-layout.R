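test_that("presets fix the documented exponents and enforce a > r", {
  expect_equal(layout_params("fr")[c("a", "r")], list(a = 2, r = -1))
  expect_equal(layout_params("linlog")[c("a", "r")], list(a = 0, r = -1))
  fa2 <- layout_params("forceatlas2")
  expect_equal(fa2[c("a", "r")], list(a = 1, r = -1))
  expect_true(fa2$degree_repulsion)
  expect_error(layout_params("custom", a = -1, r = 0), "a > r")
  expect_error(layout_params("custom"), "explicit exponents")
})

test_that("pair forces follow the stated power laws", {
  decompose <- function(d, params) {
    with_att <- pair_forces(c(0, 0), c(d, 0), TRUE, params)
    no_att <- pair_forces(c(0, 0), c(d, 0), FALSE, params)
    list(attraction = with_att - no_att, repulsion = no_att)
  }
  fr <- layout_params("fr")
  f <- decompose(2, fr)
  expect_equal(f$attraction, c(4, 0))      # d^2 toward the neighbour
  expect_equal(f$repulsion, c(-1 / 2, 0))  # d^-1 away

  ll <- layout_params("linlog")
  f5 <- decompose(5, ll)
  expect_equal(f5$attraction, c(1, 0))     # d^0: distance-independent
  f9 <- decompose(9, ll)
  expect_equal(f9$attraction, c(1, 0))

  f4 <- decompose(4, fr)
  expect_equal(f4$repulsion, c(-1 / 4, 0))

  expect_error(pair_forces(c(0, 0), c(0, 0), TRUE, fr), "coincident")
  expect_error(pair_forces(c(0, NA), c(1, 0), TRUE, fr), "non-finite")
})

test_that("energy matches the closed form on a two-node layout", {
  g <- igraph::make_graph(~ A - B)
  P <- rbind(A = c(0, 0), B = c(1, 0))
  # fr preset at d = 1: d^3/3 - ln d = 1/3
  expect_equal(layout_energy(g, P, layout_params("fr")), 1 / 3)
  expect_error(layout_energy(g, rbind(A = c(0, 0), B = c(0, 0)),
                             layout_params("fr")),
               "coincident")
})

test_that("analytic energy gradient equals minus the net pair forces", {
  set.seed(5)
  g <- random_connected_graph(5, 0.6, 5)
  P <- matrix(stats::runif(10), 5, 2)
  rownames(P) <- igraph::V(g)$name
  for (preset in c("fr", "linlog", "forceatlas2")) {
    params <- layout_params(preset)
    grad <- oracle_energy_gradient(g, P, params)
    forces <- oracle_net_forces(g, P, params)
    expect_equal(grad, -forces, tolerance = 1e-6)
  }
})

test_that("separating two non-adjacent nodes strictly decreases the energy", {
  g <- igraph::make_graph(~ A - B, C - D)
  P <- rbind(A = c(0, 0), B = c(1, 0), C = c(0, 1), D = c(1, 1))
  params <- layout_params("fr")
  u0 <- layout_energy(g, P, params)
  # shift the C-D pair rigidly away from A-B: only non-adjacent pair
  # distances change, so pure repulsion dictates the energy change
  P2 <- P
  P2["C", ] <- P2["C", ] + c(0, 10)
  P2["D", ] <- P2["D", ] + c(0, 10)
  expect_lt(layout_energy(g, P2, params), u0)
})

test_that("energy is invariant under rigid translation", {
  g <- random_connected_graph(8, 0.5, 2)
  set.seed(2)
  P <- matrix(stats::runif(16), 8, 2)
  rownames(P) <- igraph::V(g)$name
  params <- layout_params("linlog")
  u0 <- layout_energy(g, P, params)
  u1 <- layout_energy(g, sweep(P, 2, c(13.7, -4.2), "+"), params)
  expect_equal(u0, u1, tolerance = 1e-9)
})

test_that("two-node layouts reach the analytic equilibrium distance of 1", {
  g <- igraph::make_graph(~ A - B)
  for (preset in c("fr", "linlog", "forceatlas2")) {
    ly <- run_layout(g, layout_params(preset, max_iter = 5000), seed = 3)
    d <- sqrt(sum((ly$positions["A", ] - ly$positions["B", ])^2))
    # attraction d^a balances repulsion d^r at d = 1 (unit coefficients);
    # the fa2 preset scales repulsion by (deg+1)^2 = 4, so d^(a-r) = 4
    want <- if (preset == "forceatlas2") 4^(1 / 2) else 1
    expect_equal(d, want, tolerance = 1e-3)
  }
})

test_that("K3 relaxes to an equilateral triangle of side 1", {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("A", "B", "C")
  for (preset in c("fr", "linlog")) {
    ly <- run_layout(g, layout_params(preset, max_iter = 5000), seed = 4)
    sides <- as.numeric(stats::dist(ly$positions))
    expect_equal(sides, rep(1, 3), tolerance = 1e-2)
  }
})

test_that("descent is monotone, deterministic and never ends above the initial energy", {
  g <- random_connected_graph(20, 0.2, 6)
  ly <- run_layout(g, layout_params("linlog", max_iter = 300), seed = 11)
  expect_true(all(diff(ly$energy_trace) <= 0))
  expect_lte(ly$final_energy, ly$energy_trace[[1]])
  expect_equal(ly$final_energy,
               layout_energy(g, ly$positions, ly$params), tolerance = 1e-9)
  ly2 <- run_layout(g, layout_params("linlog", max_iter = 300), seed = 11)
  expect_identical(ly$positions, ly2$positions)
  expect_true(all(is.finite(ly$positions)))
})

test_that("layout communities concord with modularity communities on planted graphs", {
  hits <- 0L
  for (seed in 1:10) {
    spec <- synthetic_spec(block_sizes = rep(25L, 4), p_in = 0.30,
                           p_out = 0.01, seed = seed)
    net <- generate_planted_network(spec)
    g <- build_network(igraph::as_edgelist(net$network))
    mod <- detect_communities(g, seed = seed)
    ly <- run_layout(g, layout_params("linlog"), seed = seed)
    sp <- extract_spatial_clusters(ly)
    if (partition_agreement(sp, mod[names(sp$membership)])$nmi >= 0.90) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 8L)
})
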