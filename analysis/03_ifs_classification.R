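#!/usr/bin/env Rscript
# Stage 3: incremental feature selection with jackknife KNN.
#
# Walks the nested prefixes of the mRMR ranking, scoring each by
# leave-one-out 1-nearest-neighbour accuracy under the cosine-type distance,
# and keeps the smallest subset within 0.01 of the best accuracy — the same
# parsimony rule that prefers a compact probe set near the curve's maximum.

suppressMessages({library(optparse); library(mrmrpath)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--dir", type = "character", default = "results/inputs"),
  make_option("--out", type = "character", default = "results"),
  make_option("--k", type = "integer", default = 1L),
  make_option("--delta", type = "double", default = 0.01))))

ds <- read_expression_table(file.path(opt$dir, "expression.tsv"),
                            file.path(opt$dir, "labels.tsv"))
rk_df <- read.delim(file.path(opt$out, "ranked_features.tsv"))
class(rk_df) <- c("ranked_features", "data.frame")

ifs <- ifs_curve(rk_df, ds, k = opt$k, delta = opt$delta)
print(ifs)
write.table(ifs$accuracies, file.path(opt$out, "ifs_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

report <- jackknife_accuracy(ds, rk_df$probe_id[seq_len(ifs$selected_size)],
                             k = opt$k)
cat(sprintf("confusion at selected size %d: TP=%d TN=%d FP=%d FN=%d (accuracy %.4f)\n",
            ifs$selected_size, report$confusion["TP"], report$confusion["TN"],
            report$confusion["FP"], report$confusion["FN"], report$accuracy))
write.table(data.frame(sample_id = ds$sample_ids, label = ds$labels,
                       predicted = unname(report$predictions)),
            file.path(opt$out, "classification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(as.character(ifs$selected_size),
           file.path(opt$out, "selected_size.txt"))
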