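# Brute-force definitional oracles, independent of the package's own code
# paths (and of igraph's algorithms wherever the package delegates to it).

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
oracle_distances <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  dimnames(D) <- dimnames(A)
  D
}

oracle_global_stats <- function(g) {
  D <- oracle_distances(g)
  finite_off <- is.finite(D) & D > 0
  list(
    avg_path_length = mean(D[finite_off]),
    diameter = max(D[is.finite(D)]),
    density = igraph::ecount(g) / choose(igraph::vcount(g), 2)
  )
}

# local clustering coefficient averaged over nodes, degree<2 contributing 0
oracle_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / choose(k, 2)
  }, numeric(1))
  mean(vals)
}

# shortest-path counts via matrix powers: walks of length d(s,t) are exactly
# the shortest paths
oracle_path_counts <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- oracle_distances(g)
  maxd <- max(D[is.finite(D)])
  powers <- vector("list", maxd + 1L)
  powers[[1L]] <- diag(nrow(A))
  for (p in seq_len(maxd)) powers[[p + 1L]] <- powers[[p]] %*% A
  sigma <- matrix(0, nrow(A), ncol(A))
  for (s in seq_len(nrow(A))) {
    for (t in seq_len(ncol(A))) {
      if (is.finite(D[s, t])) sigma[s, t] <- powers[[D[s, t] + 1L]][s, t]
    }
  }
  list(D = D, sigma = sigma)
}

# pair-normalised betweenness from the path-count oracle
oracle_betweenness <- function(g) {
  pc <- oracle_path_counts(g)
  D <- pc$D; sigma <- pc$sigma
  n <- nrow(D)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    btw[v] <- acc
  }
  btw / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(g) {
  D <- oracle_distances(g)
  finite <- is.finite(D) & D > 0
  dsum <- rowSums(D * finite)
  list(invsum = 1 / dsum, meandist = dsum / rowSums(finite))
}

# principal eigenvector of the adjacency matrix by dense eigendecomposition
oracle_eigenvector <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  ev <- eigen(A, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  v / max(v)
}

# PageRank as the solution of the dense linear system
oracle_pagerank <- function(g, damping = 0.85) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  deg <- rowSums(A)
  M <- t(A / deg) # column-stochastic for deg > 0
  p <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
  unname(p / sum(p))
}

# modularity straight from the definition: count intra-cluster edges per
# cluster from the edge list
oracle_modularity <- function(g, memb) {
  el <- igraph::as_edgelist(g, names = TRUE)
  m <- nrow(el)
  k <- 2 * m
  deg <- igraph::degree(g)
  q <- 0
  for (cl in unique(memb)) {
    members <- names(memb)[memb == cl]
    e_c <- sum(el[, 1] %in% members & el[, 2] %in% members)
    k_c <- sum(deg[members])
    q <- q + e_c / m - (k_c / k)^2
  }
  q
}

# NMI and ARI from the contingency table, direct formula evaluation
oracle_agreement <- function(p1, p2) {
  p2 <- p2[names(p1)]
  N <- table(p1, p2)
  n <- sum(N)
  a <- rowSums(N); b <- colSums(N)
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (N[i, j] > 0) {
        mi <- mi + (N[i, j] / n) * log(N[i, j] * n / (a[i] * b[j]))
      }
    }
  }
  h <- function(x) { p <- x[x > 0] / n; -sum(p * log(p)) }
  h1 <- h(a); h2 <- h(b)
  nmi <- if (h1 + h2 == 0) 1 else 2 * mi / (h1 + h2)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(N))
  exp_idx <- sum_comb(a) * sum_comb(b) / choose(n, 2)
  max_idx <- (sum_comb(a) + sum_comb(b)) / 2
  ari <- if (max_idx == exp_idx) 1 else (idx - exp_idx) / (max_idx - exp_idx)
  list(nmi = unname(nmi), ari = unname(ari))
}

# central finite differences of the layout energy w.r.t. every coordinate
oracle_energy_gradient <- function(g, P, params, h = 1e-6) {
  grad <- matrix(0, nrow(P), 2L)
  for (i in seq_len(nrow(P))) {
    for (j in 1:2) {
      Pp <- P; Pp[i, j] <- Pp[i, j] + h
      Pm <- P; Pm[i, j] <- Pm[i, j] - h
      grad[i, j] <- (layout_energy(g, Pp, params) -
                       layout_energy(g, Pm, params)) / (2 * h)
    }
  }
  grad
}

# net a-r force on every node assembled from pair_forces alone
oracle_net_forces <- function(g, P, params) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  Fm <- matrix(0, nrow(P), 2L)
  scale <- if (isTRUE(params$degree_repulsion)) igraph::degree(g) + 1 else rep(1, nrow(P))
  for (v in seq_len(nrow(P))) {
    for (w in seq_len(nrow(P))) {
      if (v == w) next
      pw <- params
      pw$repulsion_coeff <- params$repulsion_coeff * scale[v] * scale[w]
      Fm[v, ] <- Fm[v, ] + pair_forces(P[v, ], P[w, ], A[v, w] == 1, pw)
    }
  }
  Fm
}

# random connected G(n, p) graph with character node names
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}
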