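#!/usr/bin/env Rscript
# Interaction-network comparison: restrict the interaction graph to its
# largest connected component, compute degree, betweenness and average
# neighbor degree per protein, and compare chromosome groups.

library(dupscan)

data_dir <- "results/synthetic"
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

gm <- read_genome_map(file.path(data_dir, "genome_map.tsv"))
manifest <- yaml::read_yaml(file.path(data_dir, "manifest.yaml"))

edges <- read_edges(file.path(data_dir, "ppi.tsv"))
g <- largest_component(build_graph(edges))
cat(sprintf("largest component: %d of %d proteins, %d interactions\n",
            igraph::vcount(g), manifest$n_proteins, igraph::ecount(g)))

features <- node_features(g)
groups <- group_summary(features, gm)
utils::write.table(features, "results/tables/network_features.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(groups, "results/tables/network_groups.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

ranked <- groups[order(groups$mean_degree), ]
cat(sprintf("lowest mean degree: %s (%.1f +/- %.1f; planted group %s)\n",
            ranked$group[1], ranked$mean_degree[1], ranked$se_degree[1],
            manifest$planted_low_degree_group))
cat(sprintf("its mean betweenness: %.0f +/- %.0f; mean neighbor degree %.1f\n",
            ranked$mean_betweenness[1], ranked$se_betweenness[1],
            ranked$mean_avg_neighbor_degree[1]))
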