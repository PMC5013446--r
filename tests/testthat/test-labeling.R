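make_ann <- function(tier1, tier2 = list()) annotation_set(tier1, tier2)

test_that("majority labeling computes label, consistency and ties", {
  drugs <- sprintf("d%02d", 1:25)
  tier1 <- stats::setNames(as.list(rep("P", 25)), drugs)
  tier1[["d25"]] <- "Q"
  memb <- stats::setNames(rep(1L, 25), drugs)
  lab <- assign_labels(memb, make_ann(tier1))
  expect_equal(lab$label, "P")
  expect_equal(lab$consistency, 96) # 24/25
  expect_equal(lab$n_members, 25L)

  # exact tie 10/10: lexicographically smaller label wins
  drugs2 <- sprintf("e%02d", 1:20)
  tier1b <- stats::setNames(as.list(rep(c("beta", "alpha"), each = 10)), drugs2)
  lab2 <- assign_labels(stats::setNames(rep(1L, 20), drugs2), make_ann(tier1b))
  expect_equal(lab2$label, "alpha")
  expect_equal(lab2$consistency, 50)

  # no member annotated at all
  lab3 <- assign_labels(stats::setNames(1L, "x1"),
                        make_ann(list(x1 = character())))
  expect_equal(lab3$label, "unlabeled")
  expect_equal(lab3$consistency, 0)
})

test_that("drug classification follows the tier-1 / tier-2 / neither rule", {
  memb <- stats::setNames(rep(1L, 3), c("d1", "d2", "d3"))
  ann <- make_ann(
    tier1 = list(d1 = "P", d2 = "Q", d3 = "Q"),
    tier2 = list(d2 = "P", d3 = "R")
  )
  labels <- data.frame(cluster_id = "1", label = "P",
                       consistency = 33, n_members = 3L,
                       stringsAsFactors = FALSE)
  st <- classify_drugs(memb, labels, ann)
  expect_equal(st[["d1"]], "confirmed")
  expect_equal(st[["d2"]], "explained")
  expect_equal(st[["d3"]], "not_explained")
  # statuses partition the drug set
  expect_equal(sum(table(st)), 3L)
  expect_error(classify_drugs(memb, labels[0, ], ann), "labels missing")
})

test_that("concordance totals are drug-count-weighted means", {
  rows <- data.frame(n = c(10, 30), pct_confirmed = c(100, 0),
                     pct_explained = c(0, 50), pct_not_explained = c(0, 50))
  tot <- concordance_totals(rows)
  expect_equal(tot$n_total, 40)
  expect_equal(tot$pct_confirmed, 25) # 10*100/40
  expect_equal(tot$pct_explained, 38) # 1500/40 = 37.5 rounded half away
  expect_equal(tot$pct_not_explained, 38)
})

test_that("community report aggregates per-community classification counts", {
  drugs <- sprintf("d%02d", 1:40)
  topo <- stats::setNames(rep(1:2, c(10, 30)), drugs)
  mod <- stats::setNames(rep(c("DB", "VM", "G"), c(10, 20, 10)), drugs)
  cls <- stats::setNames(rep("confirmed", 40), drugs)
  cls[11:40] <- "not_explained"
  rep_ <- community_report(topo, mod, cls)
  expect_equal(rep_$rows$n, c(10L, 30L))
  expect_equal(rep_$rows$pct_confirmed, c(100, 0))
  expect_equal(rep_$rows$mod_classes, c("DB", "G,VM"))
  expect_equal(rep_$totals$pct_confirmed, 25)
  expect_equal(rep_$totals$n_total, 40)
  # row percentages sum to 100 (+-1 for rounding)
  sums <- rowSums(rep_$rows[, c("pct_confirmed", "pct_explained",
                                "pct_not_explained")])
  expect_true(all(abs(sums - 100) <= 1))

  # single community, all confirmed
  one <- community_report(stats::setNames(rep(1L, 5), drugs[1:5]),
                          stats::setNames(rep(1L, 5), drugs[1:5]),
                          stats::setNames(rep("confirmed", 5), drugs[1:5]))
  expect_equal(unlist(one$totals), c(n_total = 5, pct_confirmed = 100,
                                     pct_explained = 0, pct_not_explained = 0,
                                     pct_confirmed_overall = 100))
  expect_error(community_report(topo, mod[-1], cls), "same drugs")
})

test_that("repurposing hypotheses enumerate topo/mod labels and border drugs", {
  drugs <- c("d1", "d2", "d3")
  topo <- stats::setNames(c(1L, 1L, 2L), drugs)
  mod <- stats::setNames(c(10L, 11L, 11L), drugs)
  topo_labels <- data.frame(cluster_id = c("1", "2"), label = c("P", "R"),
                            consistency = c(50, 50), n_members = c(2L, 1L),
                            stringsAsFactors = FALSE)
  mod_labels <- data.frame(cluster_id = c("10", "11"), label = c("Q", "P"),
                           consistency = c(50, 50), n_members = c(1L, 2L),
                           stringsAsFactors = FALSE)
  cls <- stats::setNames(c("not_explained", "confirmed", "confirmed"), drugs)
  border <- data.frame(node = "d2", cluster_a = "1", cluster_b = "2",
                       ratio = 1.1, stringsAsFactors = FALSE)
  hyp <- repurposing_hypotheses(cls, topo_labels, mod_labels, border,
                                topo, mod)
  # d1 not explained in community P with modularity label Q -> two records
  expect_equal(hyp[hyp$drug == "d1", "predicted_property"], c("P", "Q"))
  expect_equal(hyp[hyp$drug == "d1", "evidence"],
               c("not_explained_topo", "not_explained_mod"))
  # d2 confirmed but on the border toward community R
  expect_equal(hyp[hyp$drug == "d2", "predicted_property"], "R")
  expect_equal(hyp[hyp$drug == "d2", "evidence"], "border")
  expect_equal(hyp$drug, sort(hyp$drug))

  # matching topo and mod labels yield one hypothesis only
  mod_labels2 <- mod_labels
  mod_labels2$label <- c("P", "P")
  hyp2 <- repurposing_hypotheses(cls, topo_labels, mod_labels2,
                                 border[0, ], topo, mod)
  expect_equal(nrow(hyp2[hyp2$drug == "d1", ]), 1L)

  # fully confirmed world, no borders -> empty list
  all_conf <- stats::setNames(rep("confirmed", 3), drugs)
  expect_equal(nrow(repurposing_hypotheses(all_conf, topo_labels, mod_labels,
                                           border[0, ], topo, mod)), 0L)
})

test_that("annotation CSV round trip preserves both tiers", {
  ann <- make_ann(
    tier1 = list(d1 = c("P", "Q"), d2 = "R"),
    tier2 = list(d2 = "P")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_setequal(back$tier1[["d1"]], c("P", "Q"))
  expect_equal(back$tier1[["d2"]], "R")
  expect_equal(back$tier2[["d2"]], "P")
})

test_that("annotation validation rejects empty property strings", {
  expect_error(annotation_set(list(d1 = "")), "non-empty")
  expect_error(annotation_set(list("P")), "named")
})
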