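# Shared configuration for the analysis workflow.
#
# One synthetic BIL study at the default geometry: 12 x 40 Mb genome,
# 20k positioned genes, two +QTL/-QTL BIL pairs x three tissues x two
# stress levels, the four canonical polymorphic/QTL regions on
# chromosomes 2, 4, 9 and 10, and a BC4F3-style mapping population of
# 450 individuals.  Every numbered script sources this file.

library(qtlconverge)

study_seed <- 20260920
study_config <- sim_config(seed = study_seed, n_genes = 20000)

bil_pairs <- list(
  pair1 = c("BIL1_plusQTL", "BIL1_minusQTL"),
  pair2 = c("BIL2_plusQTL", "BIL2_minusQTL")
)
tissues <- c("root", "leaf", "panicle")

res_dir <- "results"
data_dir <- file.path(res_dir, "data")
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

path_in_results <- function(...) file.path(res_dir, ...)
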