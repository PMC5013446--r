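#!/usr/bin/env Rscript

# Stage 2 — global network statistics and centrality rankings.
#
# Characterises the simulated interaction network the way a social-network
# analysis would: small-world statistics (average path length, diameter,
# clustering coefficient, density, average degree) and the top-10 drug
# rankings under each of the five node centralities.

suppressPackageStartupMessages(library(ddinet))

out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

g <- read_edges("results/data/edges.tsv")
s <- global_stats(g)
print(s)

utils::write.csv(
  data.frame(metric = c("n_nodes", "n_edges", "avg_path_length", "diameter",
                        "clustering_coefficient", "density", "avg_degree"),
             value = c(s$n_nodes, s$n_edges, s$avg_path_length, s$diameter,
                       s$clustering_coefficient, s$density, s$avg_degree)),
  file.path(out, "global_stats.csv"), row.names = FALSE
)

tab <- compute_centralities(g)
utils::write.csv(tab, file.path(out, "centrality.csv"), row.names = FALSE)

metrics <- c("degree", "betweenness", "closeness_meandist", "pagerank",
             "eigenvector")
top10 <- do.call(rbind, lapply(metrics, function(m) {
  r <- top_k(tab, m, 10)
  data.frame(metric = m, rank = seq_len(nrow(r)), r)
}))
utils::write.csv(top10, file.path(out, "top10_centralities.csv"),
                 row.names = FALSE)

cat("\ntop 5 drugs by degree:\n")
print(top_k(tab, "degree", 5), row.names = FALSE)
cat(sprintf("\nwrote %s/global_stats.csv, centrality.csv, top10_centralities.csv\n",
            out))
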