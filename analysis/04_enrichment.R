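#!/usr/bin/env Rscript
# Term over-representation of the planned duplication: exact hypergeometric
# upper-tail tests against the whole gene set, Benjamini-Hochberg FDR, plus
# a composition delta of planted-term membership in percentage points.

library(dupscan)

data_dir <- "results/synthetic"
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

gm <- read_genome_map(file.path(data_dir, "genome_map.tsv"))
ann <- read_annotations(file.path(data_dir, "annotations.gaf"),
                        file.path(data_dir, "ontology.obo"))
manifest <- yaml::read_yaml(file.path(data_dir, "manifest.yaml"))
selection <- readLines("results/tables/duplicated_ids.txt")

res <- term_enrichment(selection, ann, gm$protein_id, alpha = 0.05)
utils::write.table(res, "results/tables/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("term enrichment of the duplicated regions -> ",
    "results/tables/enrichment.tsv\n", sep = "")
print(utils::head(res[, c("term", "k", "K", "expected", "fold", "p", "q",
                          "significant")], 5))
planted <- unlist(manifest$planted_terms)
cat(sprintf("planted term %s ranks %d of %d (q = %.3g)\n", planted,
            match(planted, res$term), nrow(res),
            res$q[match(planted, res$term)]))

cats <- setNames(ifelse(gm$protein_id %in% ann$terms[[planted]],
                        "planted-term member", "other"), gm$protein_id)
delta <- composition_delta(selection, gm$protein_id, cats)
cat(sprintf("composition delta, selection vs genome: %+.1f pp %s\n",
            delta, names(delta)))
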