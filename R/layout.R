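#' Parameters of an attraction-repulsion (a-r) energy-model layout
#'
#' In an a-r force system, adjacent nodes attract with a force proportional
#' to \eqn{d^a} and every distinct node pair repulses with a force
#' proportional to \eqn{d^r}, where `d` is the Euclidean distance. The layout
#' is a local minimum of the corresponding energy. Named presets cover the
#' classic members of the family:
#'
#' * `"fr"` — Fruchterman-Reingold, `(a, r) = (2, -1)`;
#' * `"linlog"` — LinLog, `(a, r) = (0, -1)`, whose minima separate
#'   communities particularly cleanly;
#' * `"forceatlas2"` — an a-r approximation of ForceAtlas2 with
#'   `(a, r) = (1, -1)` and repulsion scaled per pair by
#'   `(deg(v) + 1)(deg(w) + 1)`;
#' * `"custom"` — supply `a` and `r` yourself.
#'
#' The family requires `a > r`; otherwise attraction could not balance
#' repulsion at any distance.
#'
#' @param preset One of `"fr"`, `"linlog"`, `"forceatlas2"`, `"custom"`.
#' @param a,r Attraction and repulsion exponents (used for
#'   `preset = "custom"`; presets fix them).
#' @param attraction_coeff,repulsion_coeff Positive force scale factors.
#' @param max_iter Iteration cap of the descent.
#' @param step Initial step size of the adaptive descent.
#' @param tol Convergence threshold on the maximum node displacement of an
#'   accepted step (layout units).
#' @return An object of class `ar_params`.
#' @export
layout_params <- function(preset = c("linlog", "fr", "forceatlas2", "custom"),
                          a = NULL, r = NULL,
                          attraction_coeff = 1, repulsion_coeff = 1,
                          max_iter = 1000L, step = 0.1, tol = 1e-6) {
  preset <- match.arg(preset)
  degree_repulsion <- FALSE
  if (preset == "fr") {
    a <- 2; r <- -1
  } else if (preset == "linlog") {
    a <- 0; r <- -1
  } else if (preset == "forceatlas2") {
    a <- 1; r <- -1; degree_repulsion <- TRUE
  } else if (is.null(a) || is.null(r)) {
    stop("custom preset requires explicit exponents a and r")
  }
  if (!(a > r)) stop("a-r layouts require a > r (got a = ", a, ", r = ", r, ")")
  stopifnot(attraction_coeff > 0, repulsion_coeff > 0, max_iter >= 1,
            step > 0, tol > 0)
  structure(list(
    preset = preset, a = a, r = r,
    attraction_coeff = attraction_coeff, repulsion_coeff = repulsion_coeff,
    degree_repulsion = degree_repulsion,
    max_iter = as.integer(max_iter), step = step, tol = tol
  ), class = "ar_params")
}

#' Force exerted on one node by another in the a-r model
#'
#' Returns the net force vector acting on the node at `pos_v` due to the node
#' at `pos_w`: repulsion of magnitude `repulsion_coeff * d^r` (every pair)
#' plus, if the nodes are adjacent, attraction of magnitude
#' `attraction_coeff * d^a`.
#'
#' @param pos_v,pos_w Numeric length-2 coordinates; must differ (the layout
#'   engine jitters coincident points before computing forces).
#' @param adjacent Are the two nodes connected by an edge?
#' @param params An [layout_params()] object.
#' @return Numeric length-2 force vector on `v`.
#' @export
pair_forces <- function(pos_v, pos_w, adjacent, params) {
  if (!all(is.finite(pos_v)) || !all(is.finite(pos_w))) {
    stop("non-finite coordinates")
  }
  delta <- pos_w - pos_v
  d <- sqrt(sum(delta^2))
  if (d == 0) stop("coincident points: jitter positions before computing forces")
  u <- delta / d
  f <- -params$repulsion_coeff * d^params$r * u
  if (isTRUE(adjacent)) f <- f + params$attraction_coeff * d^params$a * u
  f
}

#' Total energy of a layout under the a-r model
#'
#' The energy whose negative gradient is the a-r force field:
#' \deqn{U = c_a \sum_{(v,w) \in E} \frac{d^{a+1}}{a+1}
#'         - c_r \sum_{v < w} \frac{d^{r+1}}{r+1},}
#' with the exponent-0 limit \eqn{\ln d} replacing \eqn{d^0/0} when
#' `a = -1` (attraction) or `r = -1` (repulsion, the common case: the
#' repulsion term becomes \eqn{-c_r \ln d}). Layout minima of `U` are the
#' equilibria of the force system.
#'
#' @param network An igraph object.
#' @param positions A numeric matrix with one `(x, y)` row per node (row
#'   names = node names), or an `ar_layout` object.
#' @param params An [layout_params()] object (taken from the layout when an
#'   `ar_layout` is supplied).
#' @return Scalar energy.
#' @export
layout_energy <- function(network, positions, params = NULL) {
  if (inherits(positions, "ar_layout")) {
    if (is.null(params)) params <- positions$params
    positions <- positions$positions
  }
  if (is.null(params)) stop("params required when positions are a bare matrix")
  P <- layout_position_matrix(network, positions)
  D <- as.matrix(stats::dist(P))
  if (any(D[upper.tri(D)] == 0)) {
    stop("coincident node pair: jitter positions before evaluating the energy")
  }
  a1 <- params$a + 1
  r1 <- params$r + 1
  el <- igraph::as_edgelist(network, names = TRUE)
  d_edges <- D[cbind(match(el[, 1L], rownames(P)), match(el[, 2L], rownames(P)))]
  att_term <- if (a1 == 0) sum(log(d_edges)) else sum(d_edges^a1) / a1
  dp <- D[upper.tri(D)]
  scale <- repulsion_scale(network, params)
  S <- tcrossprod(scale)[upper.tri(D)]
  rep_term <- if (r1 == 0) sum(S * log(dp)) else sum(S * dp^r1) / r1
  params$attraction_coeff * att_term - params$repulsion_coeff * rep_term
}

repulsion_scale <- function(network, params) {
  n <- igraph::vcount(network)
  if (isTRUE(params$degree_repulsion)) igraph::degree(network) + 1 else rep(1, n)
}

layout_position_matrix <- function(network, positions) {
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(network)))
  if (is.null(rownames(positions))) {
    stopifnot(nrow(positions) == length(nodes))
    rownames(positions) <- nodes
  }
  if (!all(nodes %in% rownames(positions))) {
    stop("positions must cover every network node")
  }
  positions[nodes, , drop = FALSE]
}

#' Compute an a-r energy-model layout
#'
#' Seeded random initialisation in the unit square followed by force-directed
#' descent of the a-r energy with an adaptive step: a step that lowers the
#' energy is accepted and the step size grows by 10%; a step that would raise
#' it is rejected and the step size is halved. The run stops when the maximum
#' node displacement of an accepted step drops below `params$tol` or after
#' `params$max_iter` iterations. The final energy never exceeds the initial
#' one, and the same seed reproduces the layout exactly.
#'
#' @param network An igraph object with at least 2 nodes.
#' @param params An [layout_params()] object.
#' @param seed Integer seed for the random initialisation.
#' @return An object of class `ar_layout`: list with `positions` (matrix,
#'   row names = node names), `params`, `final_energy`, `iterations_run`,
#'   and `energy_trace` (energy after each accepted step, starting at the
#'   initial configuration).
#' @examples
#' g <- igraph::make_graph(~ A - B)
#' ly <- run_layout(g, layout_params("fr", max_iter = 2000), seed = 1)
#' sqrt(sum((ly$positions["A", ] - ly$positions["B", ])^2)) # ~1
#' @export
run_layout <- function(network, params = layout_params("linlog"), seed = 1L) {
  stopifnot(igraph::is_igraph(network), inherits(params, "ar_params"))
  n <- igraph::vcount(network)
  if (n < 2L) stop("layout needs at least 2 nodes")
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))

  set.seed(as.integer(seed))
  P <- matrix(stats::runif(2L * n), ncol = 2L)
  # break exact coincidences from the start
  dup <- duplicated(P)
  if (any(dup)) P[dup, ] <- P[dup, ] + stats::runif(2L * sum(dup), -1e-6, 1e-6)
  rownames(P) <- nodes

  el <- igraph::as_edgelist(network, names = FALSE)
  edges0 <- matrix(as.integer(el - 1L), ncol = 2L)
  s <- repulsion_scale(network, params)
  dmin <- 1e-9

  fe <- ar_forces_energy(P, edges0, params$a, params$r,
                         params$attraction_coeff, params$repulsion_coeff,
                         s, dmin)
  U <- fe$energy
  trace <- U
  step <- params$step
  iters <- 0L
  for (it in seq_len(params$max_iter)) {
    iters <- it
    disp <- step * fe$forces
    P_new <- P + disp
    if (!all(is.finite(P_new))) {
      stop("layout diverged to non-finite positions at iteration ", it)
    }
    fe_new <- ar_forces_energy(P_new, edges0, params$a, params$r,
                               params$attraction_coeff,
                               params$repulsion_coeff, s, dmin)
    if (!is.finite(fe_new$energy)) {
      stop("layout energy became non-finite at iteration ", it)
    }
    if (fe_new$energy <= U) {
      P <- P_new
      U <- fe_new$energy
      fe <- fe_new
      trace <- c(trace, U)
      step <- step * 1.1
      if (max(abs(disp)) < params$tol) break
    } else {
      step <- step / 2
      if (step < 1e-14) break
    }
  }
  rownames(P) <- nodes
  structure(list(
    positions = P,
    params = params,
    final_energy = U,
    iterations_run = iters,
    energy_trace = trace
  ), class = "ar_layout")
}

#' @export
print.ar_layout <- function(x, ...) {
  cat(sprintf("a-r layout (%s preset: a = %g, r = %g): %d nodes, %d iterations, energy %.4g\n",
              x$params$preset, x$params$a, x$params$r,
              nrow(x$positions), x$iterations_run, x$final_energy))
  invisible(x)
}

#' Export a laid-out, clustered network to GraphML
#'
#' Attaches layout coordinates (`x`, `y`) and, optionally, cluster ids and
#' labels as node attributes and writes GraphML, which visualisation tools
#' such as Gephi read directly.
#'
#' @param network An igraph object.
#' @param layout An `ar_layout` (or position matrix with node row names).
#' @param path Output path.
#' @param cluster Optional named membership vector.
#' @param label Optional named character vector of node labels.
#' @return `path`, invisibly.
#' @export
write_layout_graphml <- function(network, layout, path, cluster = NULL,
                                 label = NULL) {
  P <- if (inherits(layout, "ar_layout")) layout$positions else layout
  P <- layout_position_matrix(network, P)
  igraph::V(network)$x <- P[, 1L]
  igraph::V(network)$y <- P[, 2L]
  nodes <- rownames(P)
  if (!is.null(cluster)) {
    cluster <- partition_membership(cluster)
    igraph::V(network)$cluster <- as.character(cluster[nodes])
  }
  if (!is.null(label)) igraph::V(network)$label <- as.character(label[nodes])
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
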