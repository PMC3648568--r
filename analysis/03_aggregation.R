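#!/usr/bin/env Rscript
# Step 3 — sliding-window DEG aggregation scans.
#
# 1000 kb windows advanced by 500 kb, exact binomial test against the
# genome-wide DEG fraction (p < 0.01), merged into aggregation regions
# per (pair, tissue), plus the per-pair distinct-region counts.
# Outputs: window stats TSV, region BED per pair, counts table.

source("analysis/00_config.R")

catalog <- read_gene_catalog(file.path(data_dir, "genes.tsv"))
dir.create(path_in_results("aggregation"), showWarnings = FALSE)

distinct <- data.frame()
for (pair in names(bil_pairs)) {
  per_tissue <- list()
  for (tis in tissues) {
    calls <- read_diff_calls(path_in_results(
      "deg", sprintf("deg_%s_%s.tsv", pair, tis)))
    ws <- window_scan(catalog, calls)
    write.table(ws, path_in_results(
      "aggregation", sprintf("windows_%s_%s.tsv", pair, tis)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    per_tissue[[tis]] <- merge_regions(ws)
  }
  pair_union <- union_regions(per_tissue)
  if (nrow(pair_union)) {
    write_regions_bed(pair_union, path_in_results(
      "aggregation", sprintf("regions_%s.bed", pair)))
  }
  distinct <- rbind(distinct, data.frame(
    pair = pair, n_distinct_regions = nrow(pair_union)))
  message(sprintf("%s: %d distinct DEG aggregation region(s): %s",
                  pair, nrow(pair_union),
                  paste(format_interval_mb(pair_union$chrom,
                                           pair_union$start,
                                           pair_union$end),
                        collapse = "; ")))
}
write.table(distinct, path_in_results("aggregation",
                                      "distinct_region_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
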