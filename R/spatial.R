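#' Extract topological communities from layout geometry
#'
#' Energy-model layouts place densely interconnected drugs close together,
#' so the visual communities of a laid-out network correspond to dense
#' point groups in the plane. This operation makes that reading algorithmic
#' with density-based clustering (DBSCAN-style): points with at least
#' `min_pts` neighbours within radius `eps` are core points, density-reachable
#' points share a cluster, and unreachable points become flagged singleton
#' ("noise") clusters. The radius is relative — `eps_frac` times the
#' diagonal of the layout's bounding box — which makes the extraction
#' invariant under rigid rotation, translation and uniform scaling of the
#' layout.
#'
#' @param layout An `ar_layout` object or a position matrix with node row
#'   names.
#' @param eps_frac Neighbourhood radius as a fraction of the bounding-box
#'   diagonal. Default 0.05.
#' @param min_pts Minimum number of neighbours (excluding the point itself)
#'   for a core point. Default 4.
#' @return A list of class `spatial_partition` with `membership` (named
#'   integer vector node -> cluster id) and `noise` (named logical vector
#'   flagging singleton noise clusters).
#' @export
extract_spatial_clusters <- function(layout, eps_frac = 0.05, min_pts = 4L) {
  P <- if (inherits(layout, "ar_layout")) layout$positions else layout
  stopifnot(is.matrix(P), ncol(P) == 2L)
  n <- nrow(P)
  if (n < min_pts) stop("need at least min_pts (", min_pts, ") points")
  nodes <- rownames(P)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  diag_len <- sqrt(sum((apply(P, 2L, max) - apply(P, 2L, min))^2))
  if (diag_len == 0) stop("all points coincident: no spatial structure to cluster")
  eps <- eps_frac * diag_len

  D <- as.matrix(stats::dist(P))
  nb <- D <= eps
  diag(nb) <- FALSE
  n_nb <- rowSums(nb)
  core <- n_nb >= min_pts

  cluster <- integer(n) # 0 = unassigned
  next_id <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] != 0L || !core[i]) next
    next_id <- next_id + 1L
    # expand the cluster from this core point
    queue <- i
    cluster[i] <- next_id
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      if (!core[p]) next
      reach <- which(nb[p, ] & cluster == 0L)
      cluster[reach] <- next_id
      queue <- c(queue, reach[core[reach]])
    }
  }
  noise <- cluster == 0L
  if (any(noise)) {
    cluster[noise] <- next_id + seq_len(sum(noise))
  }
  structure(list(
    membership = stats::setNames(cluster, nodes),
    noise = stats::setNames(noise, nodes)
  ), class = "spatial_partition")
}

#' Find drugs on the border between two layout communities
#'
#' A drug whose position is nearly as close to a foreign community's
#' centroid as to its own lies in the overlap zone between the two
#' communities and is hypothesised to share both communities' properties.
#' A node in cluster `a` is a border node toward the nearest foreign
#' cluster `b` when `dist(node, centroid_b) / dist(node, centroid_a)`
#' is at most `ratio_tau`.
#'
#' @param layout An `ar_layout` object or position matrix with node row
#'   names.
#' @param partition Named membership vector (or `spatial_partition`).
#' @param ratio_tau Border threshold on the centroid-distance ratio;
#'   default 1.25, chosen so that interior nodes of well-separated
#'   communities are never flagged.
#' @return A data frame `node`, `cluster_a`, `cluster_b`, `ratio`, sorted by
#'   ratio ascending.
#' @export
find_border_nodes <- function(layout, partition, ratio_tau = 1.25) {
  P <- if (inherits(layout, "ar_layout")) layout$positions else layout
  memb <- partition_membership(partition)
  nodes <- rownames(P)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(P)))
  if (!all(nodes %in% names(memb))) stop("partition must cover every laid-out node")
  memb <- memb[nodes]
  ids <- unique(memb)
  if (length(ids) < 2L) stop("border detection needs at least 2 clusters")
  centroids <- t(vapply(ids, function(cid) {
    members <- which(memb == cid)
    if (length(members) == 0L) stop("cluster ", cid, " has no members")
    colMeans(P[members, , drop = FALSE])
  }, numeric(2L)))
  rownames(centroids) <- as.character(ids)

  out <- lapply(seq_along(nodes), function(i) {
    own <- as.character(memb[[i]])
    d <- sqrt(rowSums((centroids - matrix(P[i, ], nrow(centroids), 2L,
                                          byrow = TRUE))^2))
    d_own <- d[[own]]
    foreign <- d[setdiff(rownames(centroids), own)]
    b <- names(foreign)[which.min(foreign)]
    ratio <- if (d_own == 0) Inf else foreign[[b]] / d_own
    if (is.finite(ratio) && ratio <= ratio_tau) {
      data.frame(node = nodes[[i]], cluster_a = own, cluster_b = b,
                 ratio = ratio, stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(node = character(), cluster_a = character(),
                      cluster_b = character(), ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  out[order(out$ratio, out$node), , drop = FALSE]
}
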