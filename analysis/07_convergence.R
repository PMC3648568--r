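#!/usr/bin/env Rscript
# Step 7 — convergence report and trial yield-advantage summary.
#
# Candidates = DEGs (any tissue, either pair) inside the QTL intervals,
# flagged for overlap with the DEG aggregation regions; plus the exact
# yield-advantage ranges from the packaged trial tables.

source("analysis/00_config.R")

catalog <- read_gene_catalog(file.path(data_dir, "genes.tsv"))
intervals <- default_qtl_intervals()

deg_calls <- list()
regions <- list()
for (tis in tissues) {
  pair_calls <- lapply(names(bil_pairs), function(pair) {
    read_diff_calls(path_in_results(
      "deg", sprintf("deg_%s_%s.tsv", pair, tis)))
  })
  # pool the two pairs per tissue: a gene is a DEG if called in either
  pooled <- pair_calls[[1]]
  pooled$significant <- pair_calls[[1]]$significant |
    pair_calls[[2]]$significant
  deg_calls[[tis]] <- pooled
  ws <- window_scan(catalog, pooled)
  regions[[tis]] <- merge_regions(ws)
}

nom <- nominate_candidates(deg_calls, regions, intervals, catalog)
message(sprintf("DEGs within QTL intervals: %d; within aggregation regions too: %d",
                nom$counts[["in_qtl"]],
                nom$counts[["in_qtl_and_region"]]))
write_convergence_report(nom, path_in_results("convergence"))

t6 <- make_trial_table("table6")
ya6 <- yield_advantage(t6, check_entry = "IR64", regime = "stress",
                       significant_only = TRUE)
t5 <- make_trial_table("table5")
ya5 <- yield_advantage(t5, check_entry = "IR64", regime = "stress")
print(ya6)
print(ya5)
adv <- rbind(cbind(table = "multi_site", ya6$advantages),
             cbind(table = "irri_screens", ya5$advantages))
write.table(adv, path_in_results("yield_advantages.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("convergence report and yield advantages written under results/")
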