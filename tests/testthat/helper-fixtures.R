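# shared graph fixtures, built in code

two_triangles_bridge <- function() {
  g <- igraph::make_graph(~ A - B, B - C, C - A, D - E, E - F, F - D, A - D)
  g
}

two_cliques_bridge <- function(k = 5L) {
  g1 <- igraph::make_full_graph(k)
  igraph::V(g1)$name <- paste0("a", seq_len(k))
  g2 <- igraph::make_full_graph(k)
  igraph::V(g2)$name <- paste0("b", seq_len(k))
  g <- igraph::disjoint_union(g1, g2)
  igraph::add_edges(g, c("a1", "b1"))
}

star_graph <- function(n_leaves = 4L) {
  g <- igraph::make_star(n_leaves + 1L, mode = "undirected", center = 1L)
  igraph::V(g)$name <- c("hub", paste0("leaf", seq_len(n_leaves)))
  g
}

path_graph_abc <- function() {
  igraph::make_graph(~ A - B, B - C)
}

# two well-separated point blobs (uniform disks, so the blob radius is a
# hard bound) with known membership
blob_layout <- function(n_per = 30L, sep = 10, radius = 1, seed = 1L) {
  set.seed(seed)
  disk <- function(n, cx) {
    r <- radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(cx + r * cos(th), r * sin(th))
  }
  P <- rbind(disk(n_per, 0), disk(n_per, sep))
  rownames(P) <- sprintf("p%02d", seq_len(2L * n_per))
  list(positions = P,
       truth = stats::setNames(rep(1:2, each = n_per), rownames(P)))
}
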