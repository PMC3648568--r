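#!/usr/bin/env Rscript
# Step 4 — chip-defined polymorphic regions (SFP genotyping).
#
# Per-probe Welch test of genomic-DNA hybridization intensity between
# the BIL pair (p < 0.05), then the same 1000 kb / 500 kb aggregation
# geometry with genome-wide selection of candidate regions.  The
# selected regions are the chip-defined QTL intervals used downstream.

source("analysis/00_config.R")

intens <- as.matrix(read.delim(
  file.path(data_dir, "hybridization_log2.tsv"),
  row.names = 1, check.names = FALSE))
hyb_samples <- read.delim(file.path(data_dir, "hyb_samples.tsv"))
probes <- read_gene_catalog(file.path(data_dir, "probes.tsv"))

calls <- call_hybridization_polymorphisms(intens, hyb_samples,
                                          bil_pairs$pair1)
message(sprintf("%d / %d probes differentially hybridized at p < 0.05",
                sum(calls$significant), nrow(calls)))

regions <- chip_polymorphic_regions(calls, probes)
candidates <- attr(regions, "candidates")
message(sprintf("%d candidate region(s); %d selected after genome-wide filtering:",
                nrow(candidates), nrow(regions)))
message(paste(format_interval_mb(regions$chrom, regions$start,
                                 regions$end), collapse = "; "))

dir.create(path_in_results("chip"), showWarnings = FALSE)
write_diff_calls(calls, path_in_results("chip", "sfp_calls.tsv"))
write.table(candidates, path_in_results("chip", "candidate_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
iv <- qtl_intervals(
  name = sprintf("chipQTL_%s_%.1fMb", regions$chrom,
                 regions$start / 1e6),
  chrom = regions$chrom, start = regions$start, end = regions$end,
  source = "chip_defined"
)
write.table(iv, path_in_results("chip", "chip_qtl_intervals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (nrow(regions)) {
  write_regions_bed(regions, path_in_results("chip",
                                             "chip_regions.bed"))
}
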