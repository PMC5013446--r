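#' Modularity of a partition
#'
#' Quality score of a node partition: the fraction of edges that fall inside
#' clusters minus the fraction expected if edges were wired at random while
#' preserving node degrees,
#' \deqn{Q = \sum_C \left[\frac{|E_C|}{|E|} - \left(\frac{k_C}{k}\right)^2\right],}
#' where \eqn{|E_C|} is the number of edges inside cluster \eqn{C}, \eqn{|E|}
#' the total number of edges, \eqn{k_C} the total degree of the cluster's
#' nodes and \eqn{k = 2|E|} the total degree of the network.
#'
#' @param network An igraph object with at least one edge.
#' @param partition Named vector mapping every node name to a cluster id.
#' @return The modularity score `Q` (dimensionless; at most 1, can be
#'   negative).
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("A", "B", "C")
#' modularity_score(g, c(A = 1, B = 1, C = 1)) # 0
#' @export
modularity_score <- function(network, partition) {
  stopifnot(igraph::is_igraph(network))
  if (igraph::ecount(network) == 0L) stop("modularity undefined for an edgeless network")
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(network)))
  if (!all(nodes %in% names(partition))) {
    stop("partition must cover every network node")
  }
  memb <- as.character(partition[nodes])
  m <- igraph::ecount(network)
  k_total <- 2 * m
  el <- igraph::as_edgelist(network, names = TRUE)
  cl_of <- stats::setNames(memb, nodes)
  # per-cluster intra-edge counts and total degrees
  same <- cl_of[el[, 1L]] == cl_of[el[, 2L]]
  e_c <- table(factor(cl_of[el[same, 1L]], levels = unique(memb)))
  deg <- igraph::degree(network)
  k_c <- tapply(deg[nodes], memb, sum)
  k_c <- k_c[names(e_c)]
  sum(as.numeric(e_c) / m - (as.numeric(k_c) / k_total)^2)
}

#' Detect communities by greedy modularity maximisation
#'
#' Runs multilevel (Louvain) greedy maximisation of the modularity score in
#' [modularity_score()]. The node sweep order is randomised, so a seed makes
#' the result reproducible. The returned partition never scores below the
#' trivial all-in-one or all-singleton partitions.
#'
#' @param network An igraph object with at least one edge.
#' @param seed Integer seed controlling the randomised sweep order.
#' @param resolution Resolution parameter of the modularity objective;
#'   1 recovers the standard objective.
#' @return A named integer vector mapping node name to cluster id
#'   (consecutive ids starting at 1), with attribute `"Q"` holding the
#'   modularity of the returned partition (computed at resolution 1 with
#'   [modularity_score()]).
#' @export
detect_communities <- function(network, seed = 1L, resolution = 1.0) {
  stopifnot(igraph::is_igraph(network))
  if (igraph::ecount(network) == 0L) stop("community detection undefined for an edgeless network")
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(igraph::vcount(network)))
    igraph::V(network)$name <- nodes
  }
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(network, resolution = resolution)
  memb <- igraph::membership(comm)
  partition <- stats::setNames(as.integer(memb), nodes)
  q <- modularity_score(network, partition)
  # guard: never return worse than the trivial partitions
  all_in_one <- stats::setNames(rep(1L, length(nodes)), nodes)
  if (q < modularity_score(network, all_in_one)) {
    partition <- all_in_one
    q <- modularity_score(network, partition)
  }
  attr(partition, "Q") <- q
  partition
}

#' Divisive community detection by iterative edge removal
#'
#' Reference divisive method: repeatedly removes the edge with the highest
#' edge betweenness until the network splits into `n_clusters` connected
#' components. Betweenness ties are broken by lexicographic edge id
#' (sorted endpoint names), making the procedure deterministic.
#'
#' @param network A connected igraph object.
#' @param n_clusters Target number of components, between 1 and the node
#'   count.
#' @return Named integer vector node -> cluster id.
#' @export
girvan_newman <- function(network, n_clusters) {
  stopifnot(igraph::is_igraph(network))
  n <- igraph::vcount(network)
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(n))
    igraph::V(network)$name <- nodes
  }
  if (n_clusters < 1L || n_clusters > n) {
    stop("n_clusters must be between 1 and the number of nodes (", n, ")")
  }
  if (igraph::components(network)$no > n_clusters) {
    stop("network already has more than n_clusters components")
  }
  g <- network
  repeat {
    comp <- igraph::components(g)
    if (comp$no >= n_clusters) break
    eb <- igraph::edge_betweenness(g, directed = FALSE)
    el <- igraph::as_edgelist(g, names = TRUE)
    key <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
    best <- which(eb == max(eb))
    best <- best[order(key[best])][1L]
    g <- igraph::delete_edges(g, best)
  }
  comp <- igraph::components(g)
  stats::setNames(as.integer(comp$membership[nodes]), nodes)
}

#' Agreement between two partitions
#'
#' Normalised mutual information and adjusted Rand index between two
#' partitions of the same node set. Identical partitions score 1 on both.
#'
#' @param p1,p2 Named cluster-membership vectors over the same node names.
#' @return A list with elements `nmi` and `ari`.
#' @export
partition_agreement <- function(p1, p2) {
  p1 <- partition_membership(p1)
  p2 <- partition_membership(p2)
  if (is.null(names(p1)) || is.null(names(p2)) ||
      !setequal(names(p1), names(p2))) {
    stop("partitions must cover the same node set")
  }
  p2 <- p2[names(p1)]
  a <- as.integer(factor(p1))
  b <- as.integer(factor(p2))
  list(
    nmi = igraph::compare(a, b, method = "nmi"),
    ari = igraph::compare(a, b, method = "adjusted.rand")
  )
}

# Accept either a bare named membership vector or a list carrying one
# (e.g. the value of extract_spatial_clusters()).
partition_membership <- function(p) {
  if (is.list(p) && !is.null(p$membership)) p <- p$membership
  p
}
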