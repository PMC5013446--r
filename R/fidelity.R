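#' Statistical network fidelity
#'
#' Similarity score between two networks summarised by the same ordered set
#' of global metrics (e.g. average path length, clustering coefficient,
#' average degree, density, diameter, modularity). Each metric pair
#' contributes its relative agreement and the score is the mean over the
#' `n` metrics:
#' \deqn{\varphi = \frac{1}{n} \sum_{i=1}^{n}
#'   \left[1 - \frac{|m_i - m'_i|}{\max(m_i, m'_i)}\right].}
#' \eqn{\varphi} lies in `[0, 1]`, with 1 meaning the metric vectors are
#' identical; a pair where both metrics are 0 counts as identical.
#'
#' @param reference,compared Named non-negative numeric vectors with
#'   identical names in identical order.
#' @return The fidelity score, a scalar in `[0, 1]`.
#' @examples
#' compute_fidelity(c(L = 2), c(L = 4)) # 0.5
#' @export
compute_fidelity <- function(reference, compared) {
  if (length(reference) < 1L || length(reference) != length(compared) ||
      is.null(names(reference)) || is.null(names(compared)) ||
      !identical(names(reference), names(compared))) {
    stop("metric vectors must share the same metric names in the same order")
  }
  if (any(!is.finite(reference)) || any(!is.finite(compared))) {
    stop("metric values must be finite")
  }
  if (any(reference < 0) || any(compared < 0)) {
    stop("metric values must be non-negative")
  }
  mx <- pmax(reference, compared)
  agree <- ifelse(mx == 0, 1, 1 - abs(reference - compared) / mx)
  mean(agree)
}

#' Global metric vector of a network
#'
#' Convenience constructor of the metric vector fed to
#' [compute_fidelity()]: average path length, clustering coefficient,
#' average degree, density, diameter and (when a partition is supplied)
#' modularity.
#'
#' @param network An igraph object.
#' @param partition Optional named membership vector; adds a `modularity`
#'   entry.
#' @return Named numeric vector.
#' @export
global_metric_vector <- function(network, partition = NULL) {
  s <- global_stats(network)
  v <- c(avg_path_length = s$avg_path_length,
         clustering_coefficient = s$clustering_coefficient,
         avg_degree = s$avg_degree,
         density = s$density,
         diameter = s$diameter)
  if (!is.null(partition)) {
    v <- c(v, modularity = modularity_score(network,
                                            partition_membership(partition)))
  }
  v
}

#' Read/write a metric vector as JSON
#'
#' @param path JSON path (flat object metric name -> value).
#' @return `read_metric_vector()` returns a named numeric vector.
#' @export
read_metric_vector <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(v)
}

#' @rdname read_metric_vector
#' @param metrics Named numeric vector.
#' @export
write_metric_vector <- function(metrics, path) {
  jsonlite::write_json(as.list(metrics), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
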