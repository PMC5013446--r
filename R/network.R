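#' Build a drug-drug interaction network from interaction records
#'
#' Constructs an undirected simple graph from pairwise interaction records.
#' Any direction implied by the record order is ignored: reciprocal mentions
#' `(A, B)` and `(B, A)` collapse to a single edge, self-pairs are dropped,
#' and duplicate mentions are merged. Drugs left without any interaction
#' partner after this cleaning are removed unless `keep_isolates = TRUE`,
#' mirroring the usual filter that retains only drugs with at least one
#' recorded interaction.
#'
#' @param records A two-column data frame / matrix of drug identifiers, or a
#'   list of length-2 character vectors. Identifiers must be non-empty
#'   strings.
#' @param keep_isolates Keep zero-degree nodes (drugs whose only records were
#'   self-pairs)? Default `FALSE`.
#' @return An undirected simple [igraph::igraph] object whose vertex names
#'   are the drug identifiers.
#' @examples
#' g <- build_network(data.frame(a = c("A", "B"), b = c("B", "A")))
#' igraph::vcount(g) # 2
#' igraph::ecount(g) # 1
#' @export
build_network <- function(records, keep_isolates = FALSE) {
  if (is.list(records) && !is.data.frame(records)) {
    if (length(records) == 0L) stop("no interactions")
    records <- do.call(rbind, lapply(records, function(p) {
      if (length(p) != 2L) stop("each interaction record must have exactly 2 identifiers")
      as.character(p)
    }))
  }
  records <- as.matrix(records)
  if (nrow(records) == 0L) stop("no interactions")
  if (ncol(records) != 2L) stop("interaction records must have exactly 2 columns")
  mode(records) <- "character"
  if (anyNA(records) || any(!nzchar(records))) {
    stop("drug identifiers must be non-empty strings")
  }
  g <- igraph::graph_from_edgelist(records, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!keep_isolates) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  }
  g
}

#' Read or write a network as an edge list or GraphML
#'
#' `read_edges()` parses a network from disk; `write_edges()` serialises one.
#' The TSV format is a two-column tab-separated edge list with the mandatory
#' header `source<TAB>target`; GraphML goes through [igraph::read_graph()]
#' and preserves any node attributes (e.g. layout coordinates `x`, `y`,
#' cluster ids).
#'
#' @param path File path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @param keep_isolates Passed on to [build_network()] for TSV input.
#' @return `read_edges()` returns an igraph object; `write_edges()` returns
#'   `path` invisibly.
#' @export
read_edges <- function(path, format = c("tsv", "graphml"), keep_isolates = FALSE) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(igraph::as_undirected(igraph::simplify(g), mode = "collapse"))
  }
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty edge file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[[1L]] != "source" || header[[2L]] != "target") {
    stop("edge TSV must start with header 'source\\ttarget' (line 1)")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("no interactions")
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge row with ", n_fields[bad[1L]],
         " column(s) at line ", bad[1L] + 1L)
  }
  records <- cbind(
    vapply(fields, `[[`, character(1L), 1L),
    vapply(fields, `[[`, character(1L), 2L)
  )
  build_network(records, keep_isolates = keep_isolates)
}

#' @rdname read_edges
#' @param network An igraph object.
#' @export
write_edges <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(network))
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network, names = TRUE)
    colnames(el) <- c("source", "target")
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Global network statistics
#'
#' Computes the descriptive statistics used to characterise an interaction
#' network: average path length `L` (mean shortest-path distance over all
#' reachable node pairs), diameter `Dmt` (maximal shortest-path distance),
#' average local clustering coefficient `C` (nodes of degree < 2 contribute
#' 0), density `Dst`, average degree and the degree histogram. On a
#' disconnected graph path metrics are taken over within-component pairs and
#' the diameter is the maximum over components.
#'
#' @param network An igraph object with at least one node.
#' @return An object of class `global_stats`: a list with elements
#'   `n_nodes`, `n_edges`, `avg_path_length`, `diameter`,
#'   `clustering_coefficient`, `density`, `avg_degree`, `degree_histogram`
#'   (named integer vector, degree -> node count).
#' @examples
#' g <- igraph::make_full_graph(3)
#' global_stats(g)$avg_path_length # 1
#' @export
global_stats <- function(network) {
  stopifnot(igraph::is_igraph(network))
  n <- igraph::vcount(network)
  if (n < 1L) stop("network must have at least one node")
  m <- igraph::ecount(network)
  deg <- igraph::degree(network)
  if (n >= 2L && m >= 1L) {
    L <- igraph::mean_distance(network, directed = FALSE, unconnected = TRUE)
    Dmt <- igraph::diameter(network, directed = FALSE, unconnected = TRUE)
  } else {
    L <- 0
    Dmt <- 0
  }
  cc <- if (n >= 1L) {
    val <- igraph::transitivity(network, type = "localaverage", isolates = "zero")
    if (is.nan(val)) 0 else val
  } else 0
  hist <- table(factor(deg, levels = sort(unique(deg))))
  structure(list(
    n_nodes = n,
    n_edges = m,
    avg_path_length = L,
    diameter = as.numeric(Dmt),
    clustering_coefficient = cc,
    density = if (n >= 2L) m / (n * (n - 1) / 2) else 0,
    avg_degree = if (n >= 1L) 2 * m / n else 0,
    degree_histogram = stats::setNames(as.integer(hist), names(hist))
  ), class = "global_stats")
}

#' @export
print.global_stats <- function(x, ...) {
  cat("Global network statistics\n")
  cat(sprintf("  nodes: %d   edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  average path length L: %.3f   diameter Dmt: %g\n",
              x$avg_path_length, x$diameter))
  cat(sprintf("  clustering coefficient C: %.3f   density Dst: %.3f   <k>: %.3f\n",
              x$clustering_coefficient, x$density, x$avg_degree))
  invisible(x)
}
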