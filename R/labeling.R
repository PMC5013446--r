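#' Two-tier drug property annotations
#'
#' Drug properties come in two tiers: tier 1 holds the properties listed by
#' the primary database the network was built from, tier 2 holds properties
#' confirmed later by cross-checking other databases and the literature.
#' A drug whose community label appears in tier 1 is *confirmed*; one whose
#' label appears only in tier 2 is *explained*; otherwise it is
#' *not explained* and becomes a repurposing candidate.
#'
#' @param tier1,tier2 Named lists mapping drug id to a character vector of
#'   property strings (tier 2 may be missing drugs).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(tier1, tier2 = list()) {
  stopifnot(is.list(tier1), is.list(tier2))
  check_tier <- function(tier, nm) {
    if (length(tier) > 0L && is.null(names(tier))) {
      stop(nm, " must be a named list keyed by drug id")
    }
    for (props in tier) {
      if (length(props) > 0L && any(!nzchar(props))) {
        stop("property strings must be non-empty")
      }
    }
  }
  check_tier(tier1, "tier1")
  check_tier(tier2, "tier2")
  structure(list(tier1 = tier1, tier2 = tier2), class = "annotation_set")
}

#' Read/write annotations as a long-format CSV
#'
#' Columns: `drug_id`, `tier` (1 or 2), `property`.
#'
#' @param path CSV path.
#' @return `read_annotations()` returns an [annotation_set()];
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "tier", "property")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  }
  split_tier <- function(t) {
    sub <- df[df$tier == t, , drop = FALSE]
    lapply(split(sub$property, sub$drug_id), unique)
  }
  annotation_set(split_tier(1L), split_tier(2L))
}

#' @rdname read_annotations
#' @param annotations An [annotation_set()].
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  rows <- function(tier, t) {
    if (length(tier) == 0L) return(NULL)
    data.frame(
      drug_id = rep(names(tier), lengths(tier)),
      tier = t,
      property = unlist(tier, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  df <- rbind(rows(annotations$tier1, 1L), rows(annotations$tier2, 2L))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# round half away from zero (printed percentages use this convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Label clusters by their majority pharmacological property
#'
#' Each cluster receives the property that characterises the largest
#' majority of its member drugs in the tier-1 annotations; ties are broken
#' lexicographically. The label's *consistency* is the percentage of members
#' whose tier-1 set contains it, rounded to the nearest integer. A cluster
#' none of whose members carries any property is labeled `"unlabeled"` with
#' consistency 0.
#'
#' @param partition Named membership vector (or `spatial_partition`).
#' @param annotations An [annotation_set()].
#' @param tier Annotation tier used for labeling (tier 1, the primary
#'   database).
#' @return A data frame `cluster_id`, `label`, `consistency`, `n_members`.
#' @export
assign_labels <- function(partition, annotations, tier = 1L) {
  stopifnot(inherits(annotations, "annotation_set"), tier == 1L)
  memb <- partition_membership(partition)
  if (is.null(names(memb))) stop("partition must be a named membership vector")
  tier_map <- annotations$tier1
  ids <- sort(unique(memb))
  out <- lapply(ids, function(cid) {
    members <- names(memb)[memb == cid]
    props <- unlist(lapply(members, function(d) unique(tier_map[[d]])),
                    use.names = FALSE)
    if (length(props) == 0L) {
      return(data.frame(cluster_id = as.character(cid), label = "unlabeled",
                        consistency = 0, n_members = length(members),
                        stringsAsFactors = FALSE))
    }
    counts <- table(props)
    best <- sort(names(counts)[counts == max(counts)])[[1L]]
    data.frame(
      cluster_id = as.character(cid),
      label = best,
      consistency = as.numeric(round_half_away(100 * max(counts) / length(members))),
      n_members = length(members),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Classify drugs as confirmed / explained / not explained
#'
#' A drug is `confirmed` when its community's label appears among its tier-1
#' properties, `explained` when the label appears only among its tier-2
#' properties, and `not_explained` otherwise. Not-explained drugs are the
#' repurposing candidates: the community label is a property the network
#' topology predicts for them but no source yet lists.
#'
#' @param topo_partition Named membership vector of the topological
#'   communities (or `spatial_partition`).
#' @param topo_labels Label table from [assign_labels()] covering every
#'   cluster of `topo_partition`.
#' @param annotations An [annotation_set()].
#' @return Named character vector drug -> status.
#' @export
classify_drugs <- function(topo_partition, topo_labels, annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  memb <- partition_membership(topo_partition)
  if (is.null(names(memb))) stop("partition must be a named membership vector")
  lab <- stats::setNames(topo_labels$label, topo_labels$cluster_id)
  missing_cl <- setdiff(as.character(unique(memb)), names(lab))
  if (length(missing_cl) > 0L) {
    stop("labels missing for cluster(s): ", paste(missing_cl, collapse = ", "))
  }
  status <- vapply(names(memb), function(d) {
    label <- lab[[as.character(memb[[d]])]]
    if (label %in% annotations$tier1[[d]]) "confirmed"
    else if (label %in% annotations$tier2[[d]]) "explained"
    else "not_explained"
  }, character(1L))
  status
}

#' Weighted concordance totals over community rows
#'
#' Aggregates per-community percentages into network-wide totals as
#' drug-count-weighted means, rounded to the nearest integer (half away from
#' zero) — the arithmetic behind a community accounting table's bottom row.
#'
#' @param rows Data frame with columns `n`, `pct_confirmed`, `pct_explained`,
#'   `pct_not_explained`.
#' @return List `n_total`, `pct_confirmed`, `pct_explained`,
#'   `pct_not_explained`, plus `pct_confirmed_overall` =
#'   confirmed + explained (the share of drugs whose predicted property is
#'   supported by any source).
#' @export
concordance_totals <- function(rows) {
  need <- c("n", "pct_confirmed", "pct_explained", "pct_not_explained")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns: ", paste(need, collapse = ", "))
  }
  n_total <- sum(rows$n)
  wmean <- function(p) as.numeric(round_half_away(sum(rows$n * p) / n_total))
  conf <- wmean(rows$pct_confirmed)
  expl <- wmean(rows$pct_explained)
  list(
    n_total = n_total,
    pct_confirmed = conf,
    pct_explained = expl,
    pct_not_explained = wmean(rows$pct_not_explained),
    pct_confirmed_overall = as.numeric(round_half_away(
      sum(rows$n * (rows$pct_confirmed + rows$pct_explained)) / n_total))
  )
}

#' Per-community concordance report
#'
#' For each topological community, reports its size, the modularity classes
#' represented among its members, and the percentages of members that are
#' confirmed / explained / not explained; totals are drug-count-weighted
#' means of the row percentages.
#'
#' @param topo_partition Named membership vector of topological communities.
#' @param mod_partition Named membership vector of modularity classes over
#'   the same drugs.
#' @param classification Named status vector from [classify_drugs()].
#' @return An object of class `concordance_report`: list with `rows` (data
#'   frame `community_id`, `mod_classes`, `n`, `pct_confirmed`,
#'   `pct_explained`, `pct_not_explained`) and `totals` (see
#'   [concordance_totals()]).
#' @export
community_report <- function(topo_partition, mod_partition, classification) {
  topo <- partition_membership(topo_partition)
  mod <- partition_membership(mod_partition)
  if (!setequal(names(topo), names(mod))) {
    stop("partitions must cover the same drugs")
  }
  if (!all(names(topo) %in% names(classification))) {
    stop("classification must cover every drug in the partition")
  }
  ids <- sort(unique(topo))
  rows <- lapply(ids, function(cid) {
    members <- names(topo)[topo == cid]
    if (length(members) == 0L) stop("empty community: ", cid)
    st <- classification[members]
    pct <- function(s) as.numeric(round_half_away(100 * sum(st == s) / length(members)))
    data.frame(
      community_id = as.character(cid),
      mod_classes = paste(sort(unique(as.character(mod[members]))),
                          collapse = ","),
      n = length(members),
      pct_confirmed = pct("confirmed"),
      pct_explained = pct("explained"),
      pct_not_explained = pct("not_explained"),
      stringsAsFactors = FALSE
    )
  })
  rows <- do.call(rbind, rows)
  structure(list(rows = rows, totals = concordance_totals(rows)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Community concordance report\n")
  print(x$rows, row.names = FALSE)
  with(x$totals, cat(sprintf(
    "totals: n = %d | confirmed %d%% | explained %d%% | not explained %d%% (overall confirmed %d%%)\n",
    n_total, pct_confirmed, pct_explained, pct_not_explained,
    pct_confirmed_overall)))
  invisible(x)
}

#' Generate drug repurposing hypotheses
#'
#' Two topology-driven hypothesis sources:
#' * every *not explained* drug may actually carry the property its
#'   topological community is labeled with, and — when different — the
#'   property its modularity class is labeled with;
#' * every *border* drug (between two layout communities) may share the
#'   neighbouring community's property.
#'
#' @param classification Named status vector from [classify_drugs()].
#' @param topo_labels,mod_labels Label tables from [assign_labels()] for the
#'   topological and modularity partitions.
#' @param border_nodes Data frame from [find_border_nodes()] (may be empty).
#' @param topo_partition,mod_partition The corresponding membership vectors.
#' @return A data frame `drug`, `predicted_property`, `evidence`
#'   (`not_explained_topo`, `not_explained_mod` or `border`), deduplicated
#'   and sorted by drug id.
#' @export
repurposing_hypotheses <- function(classification, topo_labels, mod_labels,
                                   border_nodes, topo_partition,
                                   mod_partition) {
  topo <- partition_membership(topo_partition)
  mod <- partition_membership(mod_partition)
  topo_lab <- stats::setNames(topo_labels$label, topo_labels$cluster_id)
  mod_lab <- stats::setNames(mod_labels$label, mod_labels$cluster_id)

  out <- list()
  ne <- names(classification)[classification == "not_explained"]
  for (d in ne) {
    tl <- topo_lab[[as.character(topo[[d]])]]
    ml <- mod_lab[[as.character(mod[[d]])]]
    out[[length(out) + 1L]] <- data.frame(
      drug = d, predicted_property = tl, evidence = "not_explained_topo",
      stringsAsFactors = FALSE)
    if (!identical(ml, tl)) {
      out[[length(out) + 1L]] <- data.frame(
        drug = d, predicted_property = ml, evidence = "not_explained_mod",
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(border_nodes) && nrow(border_nodes) > 0L) {
    for (i in seq_len(nrow(border_nodes))) {
      d <- border_nodes$node[[i]]
      nl <- topo_lab[[as.character(border_nodes$cluster_b[[i]])]]
      out[[length(out) + 1L]] <- data.frame(
        drug = d, predicted_property = nl, evidence = "border",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(drug = character(), predicted_property = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$drug, res$predicted_property, res$evidence), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
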