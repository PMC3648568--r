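make_expr_fixture <- function(seed = 1, n_genes = 200) {
  cfg <- sim_config(seed = seed, n_chromosomes = 2,
                    chromosome_length_bp = 5e6, n_genes = n_genes,
                    background_deg_rate = 0,
                    hotspots = qtl_intervals(character(0), character(0),
                                             numeric(0), numeric(0)),
                    polymorphic_blocks = qtl_intervals(character(0),
                                                       character(0),
                                                       numeric(0),
                                                       numeric(0)))
  cfg
}

test_that("welch_t_rows matches the closed-form Welch oracle to 1e-10", {
  toys <- list(
    list(x = c(1, 2, 3), y = c(1, 2, 3)),
    list(x = c(1, 2, 3), y = c(2, 4, 9)),
    list(x = c(0.1, 0.2, 0.35), y = c(5, 5.5, 4.8)),
    list(x = rnorm(5), y = rnorm(7, 1))
  )
  for (toy in toys) {
    got <- welch_t_rows(matrix(toy$x, 1), matrix(toy$y, 1))
    ref <- welch_oracle(toy$x, toy$y)
    expect_equal(got$p_value, ref$p, tolerance = 1e-10)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    tt <- t.test(toy$x, toy$y)   # independent library cross-check
    expect_equal(got$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("equal groups give effect 0 and p = 1; degenerate zero-variance rows follow the stated rules", {
  same <- welch_t_rows(matrix(c(1, 2, 3), 1), matrix(c(1, 2, 3), 1))
  expect_equal(same$effect, 0)
  expect_equal(same$p_value, 1)
  zv <- welch_t_rows(matrix(c(2, 2, 2), 1), matrix(c(2, 2, 2), 1))
  expect_equal(zv$p_value, 1)
  zv2 <- welch_t_rows(matrix(c(2, 2, 2), 1), matrix(c(3, 3, 3), 1))
  expect_gt(zv2$p_value, 0)
  expect_lt(zv2$p_value, 1e-100)
})

test_that("swapping group labels negates the effect and preserves p", {
  set.seed(8)
  x1 <- matrix(rnorm(50 * 4), 50)
  x2 <- matrix(rnorm(50 * 4, 0.5), 50)
  a <- welch_t_rows(x1, x2)
  b <- welch_t_rows(x2, x1)
  expect_equal(a$effect, -b$effect)
  expect_equal(a$p_value, b$p_value)
})

test_that("identical expression for both lines yields zero significant DEG calls", {
  cfg <- make_expr_fixture(seed = 4)
  sim <- simulate_expression(cfg)
  expr <- sim$expression
  s <- sim$samples
  # copy the minus line's values onto the plus line, replicate by replicate
  for (tis in unique(s$tissue)) for (st in unique(s$stress)) {
    for (r in unique(s$replicate)) {
      from <- s$sample_id[s$line_id == "BIL1_minusQTL" & s$tissue == tis &
                            s$stress == st & s$replicate == r]
      to <- s$sample_id[s$line_id == "BIL1_plusQTL" & s$tissue == tis &
                          s$stress == st & s$replicate == r]
      expr[, to] <- expr[, from]
    }
  }
  calls <- call_degs(expr, s, c("BIL1_plusQTL", "BIL1_minusQTL"), "root")
  expect_equal(sum(calls$significant), 0L)
  expect_equal(calls$effect, rep(0, nrow(calls)))
})

test_that("type-I error is calibrated at both conventional thresholds under the global null", {
  set.seed(11)
  n <- 20000
  p <- welch_t_rows(matrix(rnorm(n * 6), n), matrix(rnorm(n * 6), n))$p_value
  # Satterthwaite df estimation makes the Welch test mildly conservative
  # at 6 vs 6; the p-values must be valid (never anti-conservative
  # beyond sampling noise) and close to nominal
  # (conservatism grows in the far tail, where the penalty of an
  # underestimated df is largest)
  for (alpha in c(0.05, 0.001)) {
    rate <- mean(p < alpha)
    expect_lte(rate, alpha + 2.576 * sqrt(alpha * (1 - alpha) / n))
    expect_gte(rate, if (alpha == 0.05) 0.75 * alpha else 0.4 * alpha)
  }
})

test_that("570 planted large-effect root DEGs are recalled at >= 0.9 with p < 0.001", {
  cfg <- sim_config(seed = 17, n_chromosomes = 4,
                    chromosome_length_bp = 10e6, n_genes = 5000,
                    background_deg_rate = 0)
  ids <- withr::with_seed(99, sprintf("gene_%05d", sample(5000, 570)))
  planted <- data.frame(gene_id = ids, pair = "pair1", tissue = "root",
                        stringsAsFactors = FALSE)
  sim <- simulate_expression(cfg, planted = planted)
  calls <- call_degs(sim$expression, sim$samples,
                     c("BIL1_plusQTL", "BIL1_minusQTL"), "root")
  hits <- calls$feature_id[calls$significant]
  expect_gte(mean(ids %in% hits), 0.9)
  # and false positives stay near the raw threshold
  fp <- mean(calls$significant[!calls$feature_id %in% ids])
  expect_lt(fp, 0.01)
})

test_that("per-stress contrasts are available and under-replication errors name the group", {
  cfg <- make_expr_fixture(seed = 5)
  sim <- simulate_expression(cfg)
  one <- call_degs(sim$expression, sim$samples,
                   c("BIL1_plusQTL", "BIL1_minusQTL"), "leaf",
                   stress = "FTSW_0.2")
  expect_equal(nrow(one), nrow(sim$catalog))
  keep <- sim$samples$line_id != "BIL1_minusQTL" |
    sim$samples$replicate == 1
  expect_error(
    call_degs(sim$expression, sim$samples[keep, ],
              c("BIL1_plusQTL", "BIL1_minusQTL"), "leaf",
              stress = "FTSW_0.2"),
    "BIL1_minusQTL"
  )
})

test_that("hybridization calls: empty probe set in, empty calls out; planted block probes flagged", {
  empty <- call_hybridization_polymorphisms(
    matrix(numeric(0), 0, 4,
           dimnames = list(NULL, paste0("s", 1:4))),
    data.frame(sample_id = paste0("s", 1:4),
               line_id = rep(c("a", "b"), each = 2)),
    c("a", "b")
  )
  expect_equal(nrow(empty), 0L)

  cfg <- sim_config(seed = 19, n_chromosomes = 2,
                    chromosome_length_bp = 5e6, n_genes = 500,
                    polymorphic_blocks = qtl_intervals("b", "chr1",
                                                       1e6, 2e6))
  hyb <- simulate_hybridization(cfg)
  calls <- call_hybridization_polymorphisms(
    hyb$intensity, hyb$samples, c("BIL1_plusQTL", "BIL1_minusQTL"))
  flagged <- calls$feature_id[calls$significant]
  expect_gte(mean(hyb$truth$probe_id %in% flagged), 0.95)
  bg <- setdiff(calls$feature_id, hyb$truth$probe_id)
  expect_lt(mean(bg %in% flagged), 0.12)
})

test_that("DiffCall TSV round trip preserves calls", {
  calls <- data.frame(feature_id = c("a", "b"), effect = c(1.5, -0.2),
                      p_value = c(1e-6, 0.4),
                      significant = c(TRUE, FALSE),
                      contrast = "expression_p001",
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diff_calls(calls, path)
  expect_equal(read_diff_calls(path), calls)
})
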