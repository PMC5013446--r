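#' Node centralities for an interaction network
#'
#' Computes the five centralities commonly used to rank drugs by interaction
#' potential: degree, betweenness (normalised by the number of node pairs
#' `(n-1)(n-2)/2`), closeness in two variants, eigenvector centrality
#' (power iteration, max-normalised so the top node scores 1) and PageRank.
#'
#' The two closeness variants exist because "closeness" is reported under two
#' conventions: `closeness_invsum` is the inverse of the sum of shortest-path
#' distances from the node (values below 1; larger is more central), while
#' `closeness_meandist` is the mean shortest-path distance (values above 1;
#' smaller is more central, and it is ranked ascending by [top_k()]). On a
#' disconnected graph both are computed over reachable pairs only.
#'
#' @param network An igraph object with at least 2 nodes.
#' @param damping PageRank damping factor; default 0.85.
#' @param tol Convergence tolerance of the eigenvector power iteration.
#' @param max_iter Iteration cap for the power iteration; exceeding it is an
#'   error reporting the iteration count.
#' @return A data frame of class `centrality_table` with one row per node and
#'   columns `node`, `degree`, `betweenness`, `closeness_invsum`,
#'   `closeness_meandist`, `eigenvector`, `pagerank`.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected", center = 1)
#' igraph::V(g)$name <- c("hub", "a", "b", "c", "d")
#' tab <- compute_centralities(g)
#' tab[tab$node == "hub", "betweenness"] # 1
#' @export
compute_centralities <- function(network, damping = 0.85, tol = 1e-10,
                                 max_iter = 10000L) {
  stopifnot(igraph::is_igraph(network))
  n <- igraph::vcount(network)
  if (n < 2L) stop("centralities need at least 2 nodes")
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))

  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, directed = FALSE, normalized = TRUE)

  d <- igraph::distances(network)
  finite <- is.finite(d) & d > 0
  dsum <- rowSums(d * finite)
  reach <- rowSums(finite)
  closeness_invsum <- ifelse(dsum > 0, 1 / dsum, 0)
  closeness_meandist <- ifelse(reach > 0, dsum / reach, 0)

  eig <- power_iteration_eigenvector(network, tol = tol, max_iter = max_iter)
  pr <- igraph::page_rank(network, damping = damping)$vector

  structure(
    data.frame(
      node = nodes,
      degree = as.numeric(deg),
      betweenness = as.numeric(btw),
      closeness_invsum = as.numeric(closeness_invsum),
      closeness_meandist = as.numeric(closeness_meandist),
      eigenvector = as.numeric(eig),
      pagerank = as.numeric(pr),
      stringsAsFactors = FALSE
    ),
    class = c("centrality_table", "data.frame")
  )
}

# Max-normalised principal eigenvector of the adjacency matrix by power
# iteration. Deterministic (starts from the uniform vector). Iterates on
# A + I: same eigenvectors, but the spectral shift prevents the oscillation
# power iteration suffers on bipartite graphs (where eigenvalues come in
# +/- pairs).
power_iteration_eigenvector <- function(network, tol = 1e-10, max_iter = 10000L) {
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    nrm <- max(abs(y))
    if (nrm == 0) return(rep(0, n)) # edgeless graph
    y <- y / nrm
    if (max(abs(y - x)) < tol) {
      return(y / max(y))
    }
    x <- y
  }
  stop("eigenvector power iteration did not converge after ", max_iter,
       " iterations")
}

#' Top-k ranking of nodes by a centrality metric
#'
#' @param table A `centrality_table` from [compute_centralities()].
#' @param metric One of `"degree"`, `"betweenness"`, `"closeness_invsum"`,
#'   `"closeness_meandist"`, `"eigenvector"`, `"pagerank"`.
#' @param k Number of entries to return; values larger than the node count
#'   return the full ranking.
#' @return A data frame `node`, `value` ranked best-first: descending for
#'   every metric except `closeness_meandist` (mean distance: smaller is more
#'   central, so ascending). Ties are broken by lexicographic node id.
#' @export
top_k <- function(table, metric, k = 10L) {
  valid <- c("degree", "betweenness", "closeness_invsum",
             "closeness_meandist", "eigenvector", "pagerank")
  if (!is.character(metric) || length(metric) != 1L || !(metric %in% valid)) {
    stop("unknown metric '", metric, "'; valid metrics: ",
         paste(valid, collapse = ", "))
  }
  stopifnot(k >= 1L)
  v <- table[[metric]]
  decreasing <- metric != "closeness_meandist"
  ord <- order(if (decreasing) -v else v, table$node)
  ord <- ord[seq_len(min(k, nrow(table)))]
  data.frame(node = table$node[ord], value = v[ord], stringsAsFactors = FALSE)
}
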