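#!/usr/bin/env Rscript
# Step 2 — per-gene differential expression between +QTL and -QTL BILs.
#
# Welch t per gene, pooling the two stress levels as line replicates,
# at the expression convention p < 0.001; one DiffCall table per
# (BIL pair, tissue) under results/deg/.

source("analysis/00_config.R")

expr <- as.matrix(read.delim(file.path(data_dir, "expression_log2.tsv"),
                             row.names = 1, check.names = FALSE))
samples <- read.delim(file.path(data_dir, "samples.tsv"))
dir.create(path_in_results("deg"), showWarnings = FALSE)

counts <- data.frame()
for (pair in names(bil_pairs)) {
  for (tis in tissues) {
    calls <- call_degs(expr, samples, bil_pairs[[pair]], tis)
    write_diff_calls(calls, path_in_results(
      "deg", sprintf("deg_%s_%s.tsv", pair, tis)))
    counts <- rbind(counts, data.frame(
      pair = pair, tissue = tis, n_deg = sum(calls$significant)))
  }
}
write.table(counts, path_in_results("deg", "deg_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("DEG counts by pair and tissue:")
print(counts, row.names = FALSE)
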