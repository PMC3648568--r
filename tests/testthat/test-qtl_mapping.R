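planted_interval <- function(r2, chrom = "chr1", lo = 4e6, hi = 5e6,
                             name = "q") {
  iv <- qtl_intervals(name, chrom, lo, hi)
  iv$r_squared <- r2
  iv
}

test_that("constant phenotype gives LOD 0 at every marker and every pseudomarker", {
  mp <- simulate_mapping_population(small_map_config(3))
  y <- rep(1500, length(mp$pheno))
  sc <- single_marker_scan(mp$geno, y, mp$map)
  expect_true(all(sc$LOD == 0))
  isc <- interval_scan(mp$geno, y, mp$map)
  expect_true(all(isc$LOD == 0))
})

test_that("LOD, F and R^2 satisfy the regression identities against lm", {
  mp <- simulate_mapping_population(
    small_map_config(5, planted = planted_interval(0.1), n = 150))
  sc <- single_marker_scan(mp$geno, mp$pheno, mp$map)
  # LOD = (n/2) log10(1 + F df1/df2)
  expect_equal(sc$LOD,
               (sc$n / 2) * log10(1 + sc$F_value / (sc$n - 2)),
               tolerance = 1e-8)
  m <- mp$truth$marker_id
  fit <- lm(mp$pheno ~ mp$geno[, m])
  expect_equal(sc$r_squared[sc$marker_id == m],
               summary(fit)$r.squared, tolerance = 1e-10)
  expect_equal(sc$additive_effect[sc$marker_id == m],
               unname(coef(fit)[2]), tolerance = 1e-10)
})

test_that("a perfectly partitioning marker hits the capped-LOD limit", {
  map <- data.frame(marker_id = c("m1", "m2"), chrom = "chr1",
                    position_bp = c(0, 1e6), position_cM = c(0, 4))
  geno <- cbind(m1 = rep(c(0, 2), each = 20),
                m2 = withr::with_seed(2, sample(c(0, 2), 40,
                                                replace = TRUE)))
  y <- rep(c(10, 30), each = 20)
  expect_warning(sc <- single_marker_scan(geno, y, map), NA)
  r <- sc[sc$marker_id == "m1", ]
  expect_equal(r$r_squared, 1 - 1e-12, tolerance = 1e-6)
  expect_equal(r$LOD, (40 / 2) * 12, tolerance = 1e-3)
  expect_equal(r$additive_effect, 10)
})

test_that("monomorphic markers are reported with LOD 0 and a warning", {
  map <- data.frame(marker_id = c("m1", "m2"), chrom = "chr1",
                    position_bp = c(0, 1e6), position_cM = c(0, 4))
  geno <- cbind(m1 = rep(0, 30), m2 = rep(c(0, 2), 15))
  y <- rnorm(30)
  expect_warning(sc <- single_marker_scan(geno, y, map), "monomorphic")
  expect_equal(sc$LOD[sc$marker_id == "m1"], 0)
})

test_that("pseudomarkers coincident with observed markers reproduce the single-marker LOD", {
  mp <- simulate_mapping_population(
    small_map_config(7, planted = planted_interval(0.15), n = 200))
  sc <- single_marker_scan(mp$geno, mp$pheno, mp$map)
  isc <- interval_scan(mp$geno, mp$pheno, mp$map)
  at_markers <- merge(sc, isc, by = c("chrom", "position_cM"))
  expect_equal(nrow(at_markers), nrow(sc))
  expect_equal(at_markers$LOD.x, at_markers$LOD.y, tolerance = 1e-8)
})

test_that("R^2 is invariant under affine phenotype rescaling; effects scale", {
  mp <- simulate_mapping_population(
    small_map_config(9, planted = planted_interval(0.12), n = 200))
  a <- single_marker_scan(mp$geno, mp$pheno, mp$map)
  b <- single_marker_scan(mp$geno, 3 * mp$pheno + 100, mp$map)
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-10)
  expect_equal(a$LOD, b$LOD, tolerance = 1e-10)
  expect_equal(3 * a$additive_effect, b$additive_effect,
               tolerance = 1e-10)
})

test_that("missing genotypes: pairwise deletion in single-marker mode, imputation in interval mode", {
  mp <- simulate_mapping_population(
    small_map_config(13, planted = planted_interval(0.15), n = 200))
  geno <- mp$geno
  withr::with_seed(1, {
    holes <- cbind(sample(200, 30, replace = TRUE),
                   sample(ncol(geno), 30, replace = TRUE))
    geno[holes] <- NA
  })
  sc <- single_marker_scan(geno, mp$pheno, mp$map)
  expect_true(any(sc$n < 200))
  isc <- interval_scan(geno, mp$pheno, mp$map)
  expect_true(all(is.finite(isc$LOD)))
  peak <- scan_peaks(isc, mp$map)
  peak_chr1 <- peak[peak$chrom == "chr1", ]
  expect_lt(abs(peak_chr1$position_bp - mp$truth$position_bp), 2e6)
})

test_that("permutation thresholds are seed-deterministic and monotone in alpha", {
  mp <- simulate_mapping_population(small_map_config(15))
  t1 <- permutation_threshold(mp$geno, mp$pheno, mp$map, n_perm = 200,
                              alpha = 0.01, seed = 7)
  t2 <- permutation_threshold(mp$geno, mp$pheno, mp$map, n_perm = 200,
                              alpha = 0.01, seed = 7)
  expect_equal(as.numeric(t1), as.numeric(t2))
  alphas <- c(0.5, 0.1, 0.05, 0.01)
  thr <- vapply(alphas, function(a) {
    as.numeric(permutation_threshold(mp$geno, mp$pheno, mp$map,
                                     n_perm = 200, alpha = a, seed = 7))
  }, 0)
  expect_true(all(diff(thr) >= 0))
  tmin <- permutation_threshold(mp$geno, mp$pheno, mp$map, n_perm = 200,
                                alpha = 1, seed = 7)
  expect_equal(as.numeric(tmin), min(attr(tmin, "max_lods")))
  expect_error(permutation_threshold(mp$geno, mp$pheno, mp$map,
                                     n_perm = 50), ">= 100")
})

test_that("composite scan with zero cofactors is the interval scan; with cofactors it separates linked QTL", {
  two <- qtl_intervals(c("qa", "qb"), "chr1", c(2e6, 17e6),
                       c(3e6, 18e6))
  two$r_squared <- c(0.15, 0.15)
  cfg <- sim_config(seed = 27, n_chromosomes = 2,
                    chromosome_length_bp = 20e6, n_genes = 50,
                    mapping_pop = list(planted_qtl = two,
                                       n_individuals = 400,
                                       marker_spacing_bp = 1e6))
  mp <- simulate_mapping_population(cfg)
  isc <- interval_scan(mp$geno, mp$pheno, mp$map)
  c0 <- composite_scan(mp$geno, mp$pheno, mp$map, n_cofactors = 0)
  expect_equal(c0$LOD, isc$LOD, tolerance = 1e-10)
  cs <- composite_scan(mp$geno, mp$pheno, mp$map, n_cofactors = 3)
  prof <- cs[cs$chrom == "chr1", ]
  truth_cM <- mp$truth$position_bp / 1e6 * 4
  valley_at <- mean(truth_cM)
  lod_near <- function(q, w = 10) {
    max(prof$LOD[abs(prof$position_cM - q) <= w])
  }
  valley <- lod_near(valley_at, w = 5)
  for (q in truth_cM) {
    expect_gt(lod_near(q), valley + 1)  # two separated peaks, not a ridge
  }
  expect_error(composite_scan(mp$geno, mp$pheno, mp$map,
                              n_cofactors = 100), "n/10")
})

test_that("genotype and map TSV round trips preserve codes including missing", {
  mp <- simulate_mapping_population(small_map_config(17, n = 30))
  geno <- mp$geno
  geno[1, 3] <- NA
  geno[2, 5] <- 1
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(geno, gpath)
  back <- read_genotypes(gpath)
  expect_equal(back, geno)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(mp$map, mpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_marker_map(mpath), mp$map)
})

test_that("scan peak summaries mirror the conventional QTL-table schema", {
  mp <- simulate_mapping_population(
    small_map_config(19, planted = planted_interval(0.2), n = 300))
  thr <- permutation_threshold(mp$geno, mp$pheno, mp$map, n_perm = 200,
                               alpha = 0.01, seed = 2)
  peaks <- scan_peaks(interval_scan(mp$geno, mp$pheno, mp$map), mp$map,
                      threshold = thr)
  expect_named(peaks, c("chrom", "position_cM", "position_bp",
                        "marker_interval", "peak_marker", "LOD",
                        "r_squared", "additive_effect"))
  expect_equal(peaks$chrom, "chr1")
  expect_match(peaks$marker_interval, "^chr1_M[0-9]+-chr1_M[0-9]+$")
})
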