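test_that("modularity matches hand arithmetic on canonical partitions", {
  g <- two_triangles_bridge()
  nodes <- igraph::V(g)$name
  all_one <- stats::setNames(rep(1L, 6), nodes)
  expect_equal(modularity_score(g, all_one), 0)

  # the two triangles: Q = 2 * (3/7 - (7/14)^2) = 5/14
  tri <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), nodes)
  expect_equal(modularity_score(g, tri), 5 / 14)

  # all-singleton partition is negative for any graph with edges
  singl <- stats::setNames(seq_along(nodes), nodes)
  expect_lt(modularity_score(g, singl), 0)
  expect_equal(modularity_score(g, singl),
               -sum((igraph::degree(g) / 14)^2))

  expect_error(modularity_score(igraph::make_empty_graph(3, directed = FALSE),
                                stats::setNames(1:3, as.character(1:3))),
               "undefined")
})

test_that("modularity agrees with the definitional oracle and igraph on random graphs", {
  for (seed in 1:5) {
    g <- random_connected_graph(30, 0.12, seed)
    set.seed(seed)
    memb <- stats::setNames(sample(1:4, 30, replace = TRUE),
                            igraph::V(g)$name)
    q <- modularity_score(g, memb)
    expect_equal(q, oracle_modularity(g, memb), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(g, memb), tolerance = 1e-12)
    expect_lte(q, 1)
  }
})

test_that("merging two clusters changes Q by the closed-form delta", {
  for (seed in 1:3) {
    g <- random_connected_graph(24, 0.15, seed)
    nodes <- igraph::V(g)$name
    set.seed(seed)
    memb <- stats::setNames(sample(1:3, 24, replace = TRUE), nodes)
    m <- igraph::ecount(g)
    el <- igraph::as_edgelist(g)
    e12 <- sum((memb[el[, 1]] == 1 & memb[el[, 2]] == 2) |
                 (memb[el[, 1]] == 2 & memb[el[, 2]] == 1))
    deg <- igraph::degree(g)
    k1 <- sum(deg[nodes[memb == 1]])
    k2 <- sum(deg[nodes[memb == 2]])
    delta <- e12 / m - 2 * k1 * k2 / (2 * m)^2
    merged <- memb
    merged[merged == 2] <- 1
    expect_equal(modularity_score(g, merged) - modularity_score(g, memb),
                 delta, tolerance = 1e-12)
  }
})

test_that("detect_communities recovers planted cliques and reports its own Q", {
  g <- two_cliques_bridge(5)
  p <- detect_communities(g, seed = 1)
  expect_equal(length(unique(p)), 2L)
  expect_equal(length(unique(p[paste0("a", 1:5)])), 1L)
  expect_equal(length(unique(p[paste0("b", 1:5)])), 1L)
  # Q = 2 * (10/21 - (21/42)^2)
  expect_equal(attr(p, "Q"), 2 * (10 / 21 - (21 / 42)^2))
  expect_equal(attr(p, "Q"), modularity_score(g, p))
})

test_that("detect_communities beats the trivial partitions and is seed-deterministic", {
  g <- random_connected_graph(40, 0.1, 3)
  p <- detect_communities(g, seed = 7)
  nodes <- igraph::V(g)$name
  q <- attr(p, "Q")
  expect_gte(q, modularity_score(g, stats::setNames(rep(1L, 40), nodes)))
  expect_gte(q, modularity_score(g, stats::setNames(seq_len(40), nodes)))
  p2 <- detect_communities(g, seed = 7)
  expect_identical(p, p2)
  expect_error(detect_communities(igraph::make_empty_graph(2, directed = FALSE)),
               "edgeless")
})

test_that("single edge forms one two-node cluster (Q = 0 beats singletons)", {
  g <- igraph::make_graph(~ A - B)
  p <- detect_communities(g, seed = 1)
  expect_equal(length(unique(p)), 1L)
  expect_equal(attr(p, "Q"), 0)
})

test_that("planted partitions are recovered with high NMI across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    spec <- synthetic_spec(block_sizes = rep(25L, 4), p_in = 0.30,
                           p_out = 0.01, seed = seed)
    net <- generate_planted_network(spec)
    g <- build_network(igraph::as_edgelist(net$network))
    p <- detect_communities(g, seed = seed)
    nmi <- partition_agreement(p, net$ground_truth[names(p)])$nmi
    if (nmi >= 0.95) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("girvan_newman removes the bridge first and handles the extremes", {
  g <- two_triangles_bridge()
  p <- girvan_newman(g, 2)
  expect_equal(length(unique(p)), 2L)
  expect_equal(length(unique(p[c("A", "B", "C")])), 1L)
  expect_equal(length(unique(p[c("D", "E", "F")])), 1L)

  p1 <- girvan_newman(g, 1)
  expect_equal(length(unique(p1)), 1L)

  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("A", "B", "C")
  p3 <- girvan_newman(k3, 3)
  expect_equal(length(unique(p3)), 3L)

  expect_error(girvan_newman(g, 99), "between 1 and")
})

test_that("partition agreement matches the contingency-table oracle", {
  p <- stats::setNames(rep(1:2, each = 10), sprintf("d%02d", 1:20))
  expect_equal(partition_agreement(p, p), list(nmi = 1, ari = 1))

  allone <- stats::setNames(rep(1L, 20), names(p))
  expect_equal(partition_agreement(p, allone)$nmi, 0)

  swapped <- p
  swapped[["d01"]] <- 2L
  got <- partition_agreement(p, swapped)
  want <- oracle_agreement(p, swapped)
  expect_equal(got$nmi, want$nmi, tolerance = 1e-12)
  expect_equal(got$ari, want$ari, tolerance = 1e-12)

  for (seed in 1:3) {
    set.seed(seed)
    a <- stats::setNames(sample(1:4, 30, TRUE), sprintf("x%02d", 1:30))
    b <- stats::setNames(sample(1:3, 30, TRUE), names(a))
    got <- partition_agreement(a, b)
    want <- oracle_agreement(a, b)
    expect_equal(got$nmi, want$nmi, tolerance = 1e-12)
    expect_equal(got$ari, want$ari, tolerance = 1e-12)
  }

  expect_error(partition_agreement(p, p[-1]), "same node set")
})
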