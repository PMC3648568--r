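#' Calibration and recovery experiments
#'
#' Replicated simulation experiments that measure the operating
#' characteristics of the pipeline under its own generative model:
#' type-I calibration and planted-hotspot power of the sliding-window
#' scan, chip polymorphic-region recovery, planted-QTL recovery and
#' genome-wide permutation-threshold calibration, and planted-DEG
#' recall.  These are the experiments the package's validation suite
#' and reproduction script run; they are exported so the same code path
#' serves both.
#'
#' @name calibration-experiments
NULL

#' Sliding-window type-I calibration under a null genome
#'
#' Simulates `n_seeds` independent significance-flag draws (Bernoulli
#' at `rate`) over one fixed gene catalog, scans each with
#' [window_scan()] at `alpha`, and compares the per-window rejection
#' rate with the exact expected rejection probability of the discrete
#' binomial test (the mean achievable upper-tail mass below `alpha`
#' given each window's gene count and the realized genome-wide rate).
#' The discrete test is conservative, so the fair calibration reference
#' is this expected rate, not `alpha` itself.
#'
#' @param seed Base seed (seed + i is used for draw i).
#' @param n_seeds Number of independent null genomes.
#' @param alpha Per-window level.
#' @param n_chromosomes,chromosome_length_bp,n_genes Genome geometry.
#' @param rate Null significance rate of features.
#' @return A list: `observed_rate`, `expected_rate`, `diff_mean`,
#'   `diff_ci99` (99% CI for observed - expected), `n_windows`,
#'   `n_seeds`, and the per-seed observed/expected rates.
#' @export
window_calibration_experiment <- function(seed, n_seeds = 200,
                                          alpha = 0.05,
                                          n_chromosomes = 12,
                                          chromosome_length_bp = 40e6,
                                          n_genes = 30000,
                                          rate = 0.05) {
  cfg <- sim_config(seed = seed, n_chromosomes = n_chromosomes,
                    chromosome_length_bp = chromosome_length_bp,
                    n_genes = n_genes)
  catalog <- simulate_gene_catalog(cfg)
  chrom_lengths <- stats::setNames(
    rep(chromosome_length_bp, n_chromosomes),
    paste0("chr", seq_len(n_chromosomes))
  )
  obs <- exp_r <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    flags <- with_sim_seed(seed + i,
                           stats::runif(n_genes) < rate)
    ws <- window_scan(catalog, flags, alpha = alpha,
                      chrom_lengths = chrom_lengths)
    obs[i] <- mean(ws$significant)
    r_hat <- sum(flags) / n_genes
    # smallest hit count whose exact upper tail falls below alpha, and
    # that tail mass = the window's true rejection probability
    kstar <- stats::qbinom(1 - alpha, ws$gene_count, r_hat) + 1
    pi_w <- stats::pbinom(kstar - 1, ws$gene_count, r_hat,
                          lower.tail = FALSE)
    at_alpha <- pi_w >= alpha   # boundary ties: tail not strictly below
    if (any(at_alpha)) {
      pi_w[at_alpha] <- stats::pbinom(kstar[at_alpha],
                                      ws$gene_count[at_alpha], r_hat,
                                      lower.tail = FALSE)
    }
    exp_r[i] <- mean(pi_w)
  }
  d <- obs - exp_r
  ci <- mean(d) + c(-1, 1) * 2.576 * stats::sd(d) / sqrt(n_seeds)
  list(observed_rate = mean(obs), expected_rate = mean(exp_r),
       diff_mean = mean(d), diff_ci99 = ci,
       n_windows = n_chromosomes *
         ceiling(chromosome_length_bp / 5e5),
       n_seeds = n_seeds, per_seed_observed = obs,
       per_seed_expected = exp_r)
}

#' Planted-hotspot detection power of the window scan
#'
#' Plants a hotspot over `n_hot` consecutive genes whose significance
#' rate is `fold` times the background, redraws flags `n_seeds` times,
#' and reports the fraction of draws in which at least one significant
#' window overlaps the hotspot span.
#'
#' @inheritParams window_calibration_experiment
#' @param n_hot Number of consecutive hotspot genes (default 40).
#' @param fold Rate elevation inside the hotspot (default 10).
#' @return A list with `power`, `n_seeds`, and the hotspot span.
#' @export
hotspot_power_experiment <- function(seed, n_seeds = 200, alpha = 0.05,
                                     n_chromosomes = 12,
                                     chromosome_length_bp = 40e6,
                                     n_genes = 30000, rate = 0.05,
                                     n_hot = 40, fold = 10) {
  cfg <- sim_config(seed = seed, n_chromosomes = n_chromosomes,
                    chromosome_length_bp = chromosome_length_bp,
                    n_genes = n_genes)
  catalog <- simulate_gene_catalog(cfg)
  chrom_lengths <- stats::setNames(
    rep(chromosome_length_bp, n_chromosomes),
    paste0("chr", seq_len(n_chromosomes))
  )
  chr1 <- which(catalog$chrom == "chr1")
  hot <- chr1[1000:(999 + n_hot)]
  span <- c(catalog$start[hot[1]], catalog$end[hot[n_hot]])
  hits <- logical(n_seeds)
  prob <- rep(rate, n_genes)
  prob[hot] <- min(1, fold * rate)
  for (i in seq_len(n_seeds)) {
    flags <- with_sim_seed(seed + 10000 + i,
                           stats::runif(n_genes) < prob)
    ws <- window_scan(catalog, flags, alpha = alpha,
                      chrom_lengths = chrom_lengths)
    sig <- ws[ws$significant & ws$chrom == "chr1", , drop = FALSE]
    hits[i] <- any(sig$start < span[2] & sig$end > span[1])
  }
  list(power = mean(hits), n_seeds = n_seeds, span_bp = span)
}

#' Chip polymorphic-region recovery across seeds
#'
#' Runs the hybridization simulator and
#' [chip_polymorphic_regions()] for `n_seeds` seeds of the supplied
#' configuration and scores a seed as a success when every planted
#' polymorphic block intersects exactly one selected region and no
#' selected region lies outside all planted blocks.
#'
#' @param seed Base seed.
#' @param n_seeds Number of simulated chip experiments.
#' @param config Template [sim_config()]; its seed is replaced per
#'   replicate. Default: the standard fixture with the four canonical
#'   blocks.
#' @return A list with `recovery_rate`, `n_seeds`, and the per-seed
#'   success vector.
#' @export
chip_recovery_experiment <- function(seed, n_seeds = 50,
                                     config = sim_config()) {
  blocks <- config$polymorphic_blocks
  success <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    hyb <- simulate_hybridization(cfg)
    calls <- call_hybridization_polymorphisms(
      hyb$intensity, hyb$samples,
      c("BIL1_plusQTL", "BIL1_minusQTL"))
    regions <- chip_polymorphic_regions(calls, hyb$probes)
    inter <- function(r, b) {
      regions$chrom[r] == blocks$chrom[b] &
        regions$start[r] < blocks$end[b] &
        regions$end[r] > blocks$start[b]
    }
    if (nrow(regions) == 0L) next
    hit_mat <- outer(seq_len(nrow(regions)), seq_len(nrow(blocks)),
                     Vectorize(inter))
    success[i] <- all(colSums(hit_mat) == 1) && all(rowSums(hit_mat) > 0)
  }
  list(recovery_rate = mean(success), n_seeds = n_seeds,
       per_seed = success)
}

#' Planted-QTL recovery and genome-wide detection across seeds
#'
#' Simulates the default four-QTL mapping population `n_seeds` times,
#' runs the interval scan and the permutation threshold, and records
#' for the focal QTL (default the chromosome-9 locus with requested
#' R^2 = 0.13): the estimated R^2 at the scan peak, the cM distance
#' between the peak and the planted position, and whether all planted
#' QTL exceed the threshold.
#'
#' @param seed Base seed.
#' @param n_seeds Number of replicate populations.
#' @param config Template [sim_config()] (seed replaced per replicate).
#' @param focal Name of the focal planted QTL.
#' @param n_perm Permutations per replicate for the threshold.
#' @param alpha Genome-wide level for the threshold.
#' @return A list with `r2_at_peak`, `peak_dist_cM`, `all_detected`
#'   (per-seed vectors), the focal requested R^2, and summary rates.
#' @export
qtl_recovery_experiment <- function(seed, n_seeds = 100,
                                    config = sim_config(),
                                    focal = "qDTY9.1",
                                    n_perm = 200, alpha = 0.01) {
  r2p <- dist <- numeric(n_seeds)
  all_det <- logical(n_seeds)
  requested <- NA_real_
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    mp <- simulate_mapping_population(cfg)
    truth <- mp$truth
    requested <- truth$r_squared[truth$name == focal]
    isc <- interval_scan(mp$geno, mp$pheno, mp$map)
    thr <- permutation_threshold(mp$geno, mp$pheno, mp$map,
                                 n_perm = n_perm, alpha = alpha,
                                 seed = cfg$seed + 1L)
    peaks <- scan_peaks(isc, mp$map)
    cm_per_mb <- cfg$mapping_pop$cm_per_mb
    focal_chr <- truth$chrom[truth$name == focal]
    pk <- peaks[peaks$chrom == focal_chr, ]
    r2p[i] <- pk$r_squared
    dist[i] <- abs(pk$position_cM -
                     truth$position_bp[truth$name == focal] / 1e6 *
                       cm_per_mb)
    all_det[i] <- all(vapply(seq_len(nrow(truth)), function(q) {
      peaks$LOD[peaks$chrom == truth$chrom[q]] > thr
    }, TRUE))
  }
  list(r2_at_peak = r2p, peak_dist_cM = dist, all_detected = all_det,
       requested_r2 = requested, n_seeds = n_seeds,
       r2_within_tol_rate = mean(abs(r2p - requested) <= 0.05 &
                                   dist <= 10),
       all_detected_rate = mean(all_det))
}

#' Genome-wide type-I error of the permutation threshold
#'
#' Simulates `n_reps` null populations (no planted QTL), computes the
#' permutation threshold at `alpha` with `n_perm` permutations in each,
#' and reports how often the observed genome-wide maximum LOD exceeds
#' it.  The threshold order statistic targets an exceedance probability
#' of `(n_perm + 1 - idx) / (n_perm + 1)`, reported alongside.
#'
#' @param seed Base seed.
#' @param n_reps Number of outer null replicates.
#' @param n_perm Permutations per replicate.
#' @param alpha Genome-wide level.
#' @param config Template null [sim_config()] (seed replaced per
#'   replicate); default: 3 chromosomes x 11 markers, n = 200.
#' @return A list with `type1_rate`, `n_reps`, `target_rate` and the
#'   per-rep exceedance vector.
#' @export
permutation_type1_experiment <- function(seed, n_reps = 500,
                                         n_perm = 200, alpha = 0.01,
                                         config = NULL) {
  if (is.null(config)) {
    empty <- qtl_intervals(character(0), character(0), numeric(0),
                           numeric(0))
    empty$r_squared <- numeric(0)
    config <- sim_config(
      seed = 1, n_chromosomes = 3, chromosome_length_bp = 10.5e6,
      n_genes = 50,
      mapping_pop = list(planted_qtl = empty, n_individuals = 200,
                         marker_spacing_bp = 1e6)
    )
  }
  exceed <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    mp <- simulate_mapping_population(cfg)
    thr <- permutation_threshold(mp$geno, mp$pheno, mp$map,
                                 n_perm = n_perm, alpha = alpha,
                                 seed = cfg$seed + 1L)
    sc <- suppressWarnings(single_marker_scan(mp$geno, mp$pheno, mp$map))
    exceed[i] <- max(sc$LOD) > thr
  }
  idx <- min(n_perm, max(1L, ceiling((1 - alpha) * (n_perm + 1))))
  list(type1_rate = mean(exceed), n_reps = n_reps,
       target_rate = (n_perm + 1 - idx) / (n_perm + 1),
       per_rep = exceed)
}

#' Recall of planted large-effect DEGs
#'
#' Plants `n_planted` root DEGs at the configured large effect, runs
#' the expression simulator and [call_degs()] at `alpha`, and reports
#' recall against the truth table and the false-positive rate among
#' unplanted genes.
#'
#' @param seed Seed.
#' @param n_genes Catalog size.
#' @param n_planted Number of planted root DEGs (default 570, a
#'   root-transcriptome-scale count).
#' @param alpha DEG threshold.
#' @return A list with `recall`, `fp_rate`, `n_planted`, `n_genes`.
#' @export
deg_recall_experiment <- function(seed, n_genes = 5000,
                                  n_planted = 570, alpha = 0.001) {
  cfg <- sim_config(seed = seed, n_chromosomes = 4,
                    chromosome_length_bp = 10e6, n_genes = n_genes,
                    background_deg_rate = 0)
  ids <- with_sim_seed(seed + 1,
                       sprintf("gene_%05d", sample(n_genes, n_planted)))
  planted <- data.frame(gene_id = ids, pair = "pair1", tissue = "root",
                        stringsAsFactors = FALSE)
  sim <- simulate_expression(cfg, planted = planted)
  calls <- call_degs(sim$expression, sim$samples,
                     c("BIL1_plusQTL", "BIL1_minusQTL"), "root",
                     alpha = alpha)
  hits <- calls$feature_id[calls$significant]
  list(recall = mean(ids %in% hits),
       fp_rate = mean(calls$significant[!calls$feature_id %in% ids]),
       n_planted = n_planted, n_genes = n_genes)
}
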