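#!/usr/bin/env Rscript
# Stage 4: shortest-path sub-network of the selected genes.
#
# Filters the interaction network to edges with confidence strictly above
# 0.8, maps the selected genes' symbols through the gene-protein table onto
# in-network seed proteins, traces one shortest path per seed pair
# (unit edge weights; lexicographic tie-break), and counts each protein's
# path-occurrence betweenness.

suppressMessages({library(optparse); library(mrmrpath)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--dir", type = "character", default = "results/inputs"),
  make_option("--out", type = "character", default = "results"),
  make_option("--threshold", type = "double", default = 0.8))))

edges <- read_edge_list(file.path(opt$dir, "ppi_edges.tsv"))
map <- read_gene_map(file.path(opt$dir, "gene_map.tsv"))
rk <- read.delim(file.path(opt$out, "ranked_features.tsv"))
n_sel <- as.integer(readLines(file.path(opt$out, "selected_size.txt")))

network <- build_network(edges, threshold = opt$threshold)
genes <- unique(rk$gene_symbol[seq_len(n_sel)])
seeds <- map_seed_proteins(genes, map, network)
paths <- shortest_paths_among_seeds(network, seeds)
bt <- betweenness_counts(paths)

cat(sprintf("sub-network: %d proteins, %d interactions from %d seed pairs\n",
            length(paths$nodes), nrow(paths$edges),
            sum(!vapply(paths$paths, is.null, logical(1)))))
cat(sprintf("largest betweenness: %s with %d\n",
            bt$protein[1], bt$betweenness[1]))

write_sif(paths, file.path(opt$out, "subnetwork.sif"))
bt$is_seed <- bt$protein %in% seeds
write.table(bt, file.path(opt$out, "betweenness.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
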