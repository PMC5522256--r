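#!/usr/bin/env Rscript
# Stage 1: generate the simulated study.
#
# Emulates the target study design: a two-class expression matrix
# (45 tumour + 45 non-tumour samples; 10 planted informative probes with a
# one-SD class shift, 10 near-duplicate redundant copies, 480 noise probes)
# and a scale-free interaction network (200 background proteins, one planted
# hub of degree 30, edge confidences in [0.85, 1]). Ground-truth probe roles
# and hub identities are written alongside the four pipeline inputs.

suppressMessages({library(optparse); library(mrmrpath)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--dir", type = "character", default = "results/inputs"))))

paths <- write_simulation(expression_sim_spec(seed = opt$seed),
                          network_sim_spec(seed = opt$seed),
                          opt$dir)

ds <- read_expression_table(paths$expression, paths$labels)
el <- read_edge_list(paths$edges)
cat(sprintf("wrote %s: %d probes x %d samples (%d tumour / %d non-tumour)\n",
            opt$dir, nrow(ds$values), ncol(ds$values),
            sum(ds$labels == 1), sum(ds$labels == 0)))
cat(sprintf("network: %d interactions among %d proteins, scores in [%.2f, %.2f]\n",
            nrow(el), length(unique(c(el$protein_a, el$protein_b))),
            min(el$score), max(el$score)))
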