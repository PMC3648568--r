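#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs.
#
# Writes the gene catalog (TSV + BED), the expression matrix and sample
# sheet, the genomic-hybridization intensities, the mapping-population
# genotypes/phenotypes/map, and the trial tables under results/data/.

source("analysis/00_config.R")

message("simulating expression experiment ...")
expr_sim <- simulate_expression(study_config)
write_gene_catalog(expr_sim$catalog, file.path(data_dir, "genes.tsv"))
write_gene_catalog(expr_sim$catalog, file.path(data_dir, "genes.bed"),
                   format = "bed")
write.table(round(expr_sim$expression, 4),
            file.path(data_dir, "expression_log2.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write.table(expr_sim$samples, file.path(data_dir, "samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(expr_sim$truth, file.path(data_dir, "planted_degs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d genes x %d samples; %d planted DEG cells",
                nrow(expr_sim$expression), ncol(expr_sim$expression),
                nrow(expr_sim$truth)))

message("simulating genomic-DNA hybridization ...")
hyb <- simulate_hybridization(study_config)
write.table(round(hyb$intensity, 4),
            file.path(data_dir, "hybridization_log2.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write.table(hyb$samples, file.path(data_dir, "hyb_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gene_catalog(hyb$probes, file.path(data_dir, "probes.tsv"))
message(sprintf("  %d probes; %d inside planted polymorphic blocks",
                nrow(hyb$probes), nrow(hyb$truth)))

message("simulating BC4F3 mapping population ...")
mp <- simulate_mapping_population(study_config)
write_genotypes(mp$geno, file.path(data_dir, "genotypes.tsv"))
write.table(mp$map, file.path(data_dir, "marker_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(individual = rownames(mp$geno),
                       gy_kg_ha = round(mp$pheno, 2)),
            file.path(data_dir, "phenotypes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mp$truth, file.path(data_dir, "planted_qtl.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d individuals x %d markers; planted QTL: %s",
                nrow(mp$geno), ncol(mp$geno),
                paste(mp$truth$name, collapse = ", ")))

message("writing trial tables ...")
for (src in c("table5", "table6")) {
  write.table(make_trial_table(src),
              file.path(data_dir, paste0(src, "_trial.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message("done; inputs under ", data_dir)
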