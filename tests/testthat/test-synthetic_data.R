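no_intervals <- function() {
  qtl_intervals(character(0), character(0), numeric(0), numeric(0))
}

small_expr_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chromosomes = 2,
             chromosome_length_bp = 5e6, n_genes = 400,
             polymorphic_blocks = qtl_intervals("b1", "chr1", 1e6, 2e6),
             ...)
}

test_that("generators are pure functions of the config (seed determinism)", {
  cfg <- small_expr_config(seed = 9)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  ha <- simulate_hybridization(cfg)
  hb <- simulate_hybridization(cfg)
  expect_identical(ha$intensity, hb$intensity)
  mpa <- simulate_mapping_population(small_map_config(4))
  mpb <- simulate_mapping_population(small_map_config(4))
  expect_identical(mpa$geno, mpb$geno)
  expect_identical(mpa$pheno, mpb$pheno)
  # and the catalog is shared across generators
  expect_identical(simulate_gene_catalog(cfg)$gene_id, a$catalog$gene_id)
})

test_that("zero DEG rate with no hotspots plants nothing", {
  cfg <- small_expr_config(seed = 2, background_deg_rate = 0,
                           hotspots = no_intervals())
  sim <- simulate_expression(cfg)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("hotspot planting rate honours the elevated rate (binomial 99% bounds)", {
  hs <- qtl_intervals("h", "chr1", 0, 5e6)
  hs$elevated_deg_rate <- 0.75
  cfg <- small_expr_config(seed = 6, background_deg_rate = 0.01,
                           hotspots = hs)
  sim <- simulate_expression(cfg)
  in_hs <- genes_in_interval(sim$catalog, hs)$gene_id
  # one (pair, tissue) cell is an independent Bernoulli(0.75) draw per gene
  planted <- subset(sim$truth, pair == "pair1" & tissue == "root")$gene_id
  n_h <- length(in_hs)
  k <- sum(in_hs %in% planted)
  bounds <- qbinom(c(0.005, 0.995), n_h, 0.75)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("planted expression effects sit on the +QTL line of the right pair and tissue", {
  planted <- data.frame(gene_id = "gene_00001", pair = "pair2",
                        tissue = "leaf", effect_log2 = 3)
  cfg <- small_expr_config(seed = 3, background_deg_rate = 0)
  sim <- simulate_expression(cfg, planted = planted)
  s <- sim$samples
  gi <- which(sim$catalog$gene_id == "gene_00001")
  hit_cols <- s$pair == "pair2" & s$tissue == "leaf" &
    s$qtl_class == "plusQTL"
  diff <- mean(sim$expression[gi, hit_cols]) -
    mean(sim$expression[gi, s$pair == "pair2" & s$tissue == "leaf" &
                          s$qtl_class == "minusQTL"])
  expect_gt(diff, 2)  # 3 minus noise
  other <- s$tissue == "root" & s$pair == "pair2"
  d2 <- mean(sim$expression[gi, other & s$qtl_class == "plusQTL"]) -
    mean(sim$expression[gi, other & s$qtl_class == "minusQTL"])
  expect_lt(abs(d2), 1)
})

test_that("hybridization truth matches the planted blocks and lines differ only there", {
  cfg <- small_expr_config(seed = 12)
  hyb <- simulate_hybridization(cfg)
  mid <- floor((hyb$probes$start + hyb$probes$end) / 2)
  inside <- hyb$probes$chrom == "chr1" & mid >= 1e6 & mid < 2e6
  expect_setequal(hyb$truth$probe_id, hyb$probes$gene_id[inside])
  plus <- hyb$samples$sample_id[hyb$samples$line_id == "BIL1_plusQTL"]
  minus <- hyb$samples$sample_id[hyb$samples$line_id == "BIL1_minusQTL"]
  gap <- rowMeans(hyb$intensity[, plus]) -
    rowMeans(hyb$intensity[, minus])
  expect_lt(abs(mean(gap[!inside])), 0.05)
  expect_gt(abs(mean(gap[inside])),
            0.8 * cfg$hyb_shift_sd_multiple * cfg$hyb_noise_sd)
})

test_that("mapping population realizes the requested QTL R^2 and genotype structure", {
  planted <- qtl_intervals("q1", "chr1", 4e6, 5e6)
  planted$r_squared <- 0.13
  cfg <- small_map_config(21, planted = planted, n = 450)
  mp <- simulate_mapping_population(cfg)
  expect_true(all(mp$geno %in% c(0, 2)))
  qm <- mp$truth$marker_id
  r2 <- cor(mp$geno[, qm], mp$pheno)^2
  expect_gte(r2, 0.10)   # requested 0.13 within +/- 0.03 at n >= 400
  expect_lte(r2, 0.16)
  # donor frequency: ~0.5 at the QTL marker, ~1/16 far from it
  expect_gt(mean(mp$geno[, qm] == 2), 0.4)
  far <- mp$map$marker_id[mp$map$chrom == "chr3"]
  freq_bg <- mean(mp$geno[, far] == 2)
  bounds <- qbinom(c(0.005, 0.995), length(far) * 450, 1 / 16) /
    (length(far) * 450)
  expect_gt(freq_bg, 0.02)
  expect_lt(freq_bg, 0.12)
  # recombination-consistent decay of linkage with distance
  mk <- mp$map$marker_id[mp$map$chrom == "chr1"]
  d <- mp$geno[, mk] / 2
  near <- cor(d[, 4], d[, 5])
  farr <- cor(d[, 4], d[, 10])
  expect_gt(near, farr)
})

test_that("requested r_squared = 0 leaves the phenotype unlinked to all markers", {
  planted <- qtl_intervals("q1", "chr1", 4e6, 5e6)
  planted$r_squared <- 0
  cfg <- small_map_config(31, planted = planted, n = 300)
  mp <- simulate_mapping_population(cfg)
  thr <- permutation_threshold(mp$geno, mp$pheno, mp$map,
                               n_perm = 200, alpha = 0.01, seed = 1)
  sc <- single_marker_scan(mp$geno, mp$pheno, mp$map)
  expect_lt(max(sc$LOD), thr)
})

test_that("config validation enforces the documented invariants", {
  expect_error(small_expr_config(background_deg_rate = 1.5), "\\[0, 1\\]")
  bad_hs <- qtl_intervals("h", "chr1", 0, 9e9)
  bad_hs$elevated_deg_rate <- 0.5
  expect_error(small_expr_config(hotspots = bad_hs), "off the simulated")
  planted <- qtl_intervals(c("a", "b"), c("chr1", "chr2"),
                           c(0, 0), c(1e6, 1e6))
  planted$r_squared <- c(0.6, 0.5)
  expect_error(small_map_config(1, planted = planted), "sum")
  expect_error(
    sim_config(mapping_pop = list(error_variance = -1)), "positive"
  )
})

test_that("trial fixtures reproduce printed cells and simulated nulls are centred at zero", {
  t6 <- make_trial_table("table6")
  expect_equal(
    t6$yield_kg_ha[t6$entry == "IR64" & t6$site == "Rajshahi" &
                     t6$regime == "stress"], 980)
  t5 <- make_trial_table("table5")
  expect_equal(
    t5$yield_kg_ha[t5$entry == "IR64" & t5$site == "DS10" &
                     t5$regime == "stress"], 636)
  cfg <- sim_config(seed = 5)
  tt <- make_trial_table("simulated", cfg)
  adv <- yield_advantage(tt, check_entry = "IR64", regime = "stress")
  m <- mean(adv$advantages$advantage_kg_ha)
  se <- sd(adv$advantages$advantage_kg_ha) /
    sqrt(nrow(adv$advantages))
  expect_lt(abs(m), 4 * se + 1)
})
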