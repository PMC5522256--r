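#!/usr/bin/env Rscript
# Stage 2: mRMR probe ranking.
#
# Ranks the 500 most informative probes by greedy mutual-information mRMR
# (relevance to the tumour phenotype minus mean redundancy with the probes
# already chosen) and writes the ranked table in the layout
# (rank, probe_id, gene_symbol, q_score).

suppressMessages({library(optparse); library(mrmrpath)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--dir", type = "character", default = "results/inputs"),
  make_option("--out", type = "character", default = "results"),
  make_option("--N", type = "integer", default = 500L))))

ds <- read_expression_table(file.path(opt$dir, "expression.tsv"),
                            file.path(opt$dir, "labels.tsv"))
ranked <- mrmr_rank(ds, N = opt$N)

dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
write.table(as.data.frame(ranked), file.path(opt$out, "ranked_features.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("ranked %d probes; top of the list:\n", nrow(ranked)))
print(head(as.data.frame(ranked), 5), row.names = FALSE)
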