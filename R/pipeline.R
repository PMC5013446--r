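#' Run the dual-clustering analysis pipeline end to end
#'
#' Executes the full procedure on one network: build the interaction network,
#' compute global statistics and centralities, detect modularity classes,
#' compute an a-r energy-model layout, extract topological communities from
#' the layout geometry, label both partitions by majority property, classify
#' every drug as confirmed / explained / not explained, assemble the
#' per-community concordance report, generate repurposing hypotheses from
#' not-explained and border drugs, and (optionally) score fidelity against a
#' reference metric vector. All randomness is funnelled through one master
#' seed, so an identical config yields an identical bundle.
#'
#' @param config A named list (or path to a YAML file holding one) with
#'   entries:
#'   * `synthetic`: arguments for [synthetic_spec()] — or instead
#'     `edges` (edge TSV path) and `annotations` (annotation CSV path);
#'   * `seed`: master seed (default 1; a synthetic spec's own seed is
#'     derived from it);
#'   * `layout`: arguments for [layout_params()] (default LinLog preset);
#'   * `eps_frac`, `min_pts`: spatial extraction parameters;
#'   * `ratio_tau`: border-drug threshold;
#'   * `resolution`: modularity resolution;
#'   * `reference_metrics`: optional named vector (or JSON path) for
#'     fidelity scoring;
#'   * `output_dir`: optional directory; when set, all artifacts plus a
#'     run manifest are written there.
#' @return A list of class `ddi_bundle` with elements `network`, `stats`,
#'   `centralities`, `mod_partition`, `layout`, `topo_partition`,
#'   `topo_labels`, `mod_labels`, `classification`, `report`, `border_nodes`,
#'   `hypotheses`, `fidelity` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ground_truth <- NULL
  if (!is.null(config$synthetic)) {
    sim <- stage("simulate", {
      args <- config$synthetic
      args$seed <- args$seed %||% seed
      spec <- do.call(synthetic_spec, args)
      net <- generate_planted_network(spec)
      ann <- generate_annotations(net$ground_truth, spec)
      list(spec = spec, network = net$network,
           ground_truth = net$ground_truth, annotations = ann)
    })
    raw_network <- sim$network
    annotations <- sim$annotations
    ground_truth <- sim$ground_truth
  } else {
    raw_network <- stage("build", {
      if (is.null(config$edges)) stop("config needs 'synthetic' or 'edges'")
      read_edges(config$edges, format = config$edge_format %||% "tsv")
    })
    annotations <- stage("labeling", {
      if (is.null(config$annotations)) stop("missing annotation file")
      read_annotations(config$annotations)
    })
  }

  network <- stage("build", {
    el <- igraph::as_edgelist(raw_network, names = TRUE)
    build_network(el)
  })
  stats_ <- stage("stats", global_stats(network))
  centr <- stage("centrality", compute_centralities(network))
  mod_partition <- stage("cluster", {
    detect_communities(network, seed = seed,
                       resolution = config$resolution %||% 1.0)
  })
  layout_args <- config$layout %||% list()
  params <- stage("layout", do.call(layout_params, layout_args))
  layout <- stage("layout", run_layout(network, params, seed = seed))
  topo_partition <- stage("communities", {
    extract_spatial_clusters(layout,
                             eps_frac = config$eps_frac %||% 0.05,
                             min_pts = config$min_pts %||% 4L)
  })
  topo_labels <- stage("label", assign_labels(topo_partition, annotations))
  mod_labels <- stage("label", assign_labels(mod_partition, annotations))
  classification <- stage("classify", {
    classify_drugs(topo_partition, topo_labels, annotations)
  })
  report <- stage("report", {
    community_report(topo_partition, mod_partition, classification)
  })
  border <- stage("communities", {
    if (length(unique(topo_partition$membership)) >= 2L) {
      find_border_nodes(layout, topo_partition,
                        ratio_tau = config$ratio_tau %||% 1.25)
    } else {
      data.frame(node = character(), cluster_a = character(),
                 cluster_b = character(), ratio = numeric())
    }
  })
  hypotheses <- stage("repurpose", {
    repurposing_hypotheses(classification, topo_labels, mod_labels, border,
                           topo_partition, mod_partition)
  })
  fidelity <- NULL
  if (!is.null(config$reference_metrics)) {
    fidelity <- stage("fidelity", {
      ref <- config$reference_metrics
      if (is.character(ref) && length(ref) == 1L) ref <- read_metric_vector(ref)
      cmp <- global_metric_vector(network, mod_partition)[names(ref)]
      if (anyNA(cmp)) stop("reference metric(s) not computable: ",
                           paste(names(ref)[is.na(cmp)], collapse = ", "))
      compute_fidelity(ref, cmp)
    })
  }

  manifest <- list(
    seed = seed,
    config = config[setdiff(names(config), "output_dir")],
    n_nodes = stats_$n_nodes,
    n_edges = stats_$n_edges,
    modularity = attr(mod_partition, "Q"),
    n_mod_classes = length(unique(mod_partition)),
    n_topo_communities = length(unique(topo_partition$membership)),
    package_version = as.character(utils::packageVersion("ddinet"))
  )

  bundle <- structure(list(
    network = network, stats = stats_, centralities = centr,
    mod_partition = mod_partition, layout = layout,
    topo_partition = topo_partition, topo_labels = topo_labels,
    mod_labels = mod_labels, classification = classification,
    report = report, border_nodes = border, hypotheses = hypotheses,
    fidelity = fidelity, ground_truth = ground_truth, manifest = manifest
  ), class = "ddi_bundle")

  if (!is.null(config$output_dir)) {
    write_bundle(bundle, config$output_dir)
  }
  bundle
}

#' @rdname run_pipeline
#' @param path Path to a YAML pipeline config.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write a pipeline bundle's artifacts to a directory
#'
#' Emits the edge list, centrality table, both partitions, label tables,
#' classification, concordance report (CSV + JSON), border report,
#' repurposing hypotheses, GraphML with layout coordinates, and a JSON run
#' manifest.
#'
#' @param bundle A `ddi_bundle` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ddi_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_edges(bundle$network, p("edges.tsv"))
  utils::write.csv(bundle$centralities, p("centrality.csv"), row.names = FALSE)
  write_partition <- function(memb, path, noise = NULL) {
    df <- data.frame(node = names(memb), cluster_id = as.character(memb),
                     stringsAsFactors = FALSE)
    if (!is.null(noise)) df$noise <- noise[df$node]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_partition(bundle$mod_partition, p("modularity_classes.tsv"))
  write_partition(bundle$topo_partition$membership,
                  p("topological_communities.tsv"),
                  noise = bundle$topo_partition$noise)
  utils::write.csv(bundle$topo_labels, p("topo_labels.csv"), row.names = FALSE)
  utils::write.csv(bundle$mod_labels, p("mod_labels.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(drug = names(bundle$classification),
               status = bundle$classification, stringsAsFactors = FALSE),
    p("classification.csv"), row.names = FALSE)
  utils::write.csv(bundle$report$rows, p("report_rows.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$report$totals, p("report_totals.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$border_nodes, p("border_nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$hypotheses, p("repurposing_hypotheses.csv"),
                   row.names = FALSE)
  write_layout_graphml(bundle$network, bundle$layout, p("network_layout.graphml"),
                       cluster = bundle$mod_partition)
  manifest <- bundle$manifest
  if (!is.null(bundle$fidelity)) manifest$fidelity <- bundle$fidelity
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
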