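# catalog with a fully controlled window: 40 genes in chr1:[0,500k)
# (covered only by the first window) plus 1160 filler genes on chr2
controlled_window_catalog <- function() {
  start1 <- seq(1000, 490000, length.out = 40)
  start2 <- seq(1000, 990000, length.out = 1160)
  gene_catalog(
    gene_id = sprintf("g%04d", 1:1200),
    chrom = rep(c("chr1", "chr2"), c(40, 1160)),
    start = c(start1, start2),
    end = c(start1, start2) + 100
  )
}

test_that("window p-value equals the exact binomial upper tail (40 genes, 30 hits, rate 0.05)", {
  catalog <- controlled_window_catalog()
  flags <- logical(1200)
  flags[1:30] <- TRUE          # 30 of the 40 chr1 genes
  flags[41:70] <- TRUE         # 30 of 1160 on chr2 -> genome rate 60/1200
  ws <- window_scan(catalog, flags, chrom_lengths = c(chr1 = 5e5,
                                                      chr2 = 1e6))
  rate <- 60 / 1200
  expect_equal(rate, 0.05)
  target <- ws[ws$chrom == "chr1" & ws$start == 0, ]
  expect_equal(target$gene_count, 40L)
  expect_equal(target$hit_count, 30L)
  k <- 30:40
  oracle <- sum(choose(40, k) * 0.05^k * 0.95^(40 - k))
  expect_equal(target$p_value, oracle, tolerance = 1e-12)
  expect_true(target$significant)
})

test_that("no significant features anywhere degenerates every window to p = 1", {
  catalog <- controlled_window_catalog()
  ws <- window_scan(catalog, logical(1200))
  expect_true(all(ws$p_value == 1))
  expect_false(any(ws$significant))
})

test_that("window tiling: interior features contribute to exactly 2 windows, clipped at chromosome ends", {
  catalog <- random_catalog(n = 400, n_chrom = 1, len = 5e6, seed = 21)
  ws <- window_scan(catalog, logical(400),
                    chrom_lengths = c(chr1 = 5e6))
  mid <- floor((catalog$start + catalog$end) / 2)
  # features with midpoint < step fall in the first window only
  n_edge <- sum(mid < 5e5)
  expect_equal(sum(ws$gene_count), 2L * (400L - n_edge) + n_edge)
  expect_true(all(ws$end - ws$start <= 1e6))
  expect_equal(max(ws$end), 5e6)
  expect_error(window_scan(catalog, logical(400), block_size_bp = 4e5,
                           step_bp = 5e5), "step")
})

test_that("adding a hit to a window at fixed genome-wide rate lowers its p-value", {
  catalog <- controlled_window_catalog()
  flags_a <- logical(1200); flags_a[1:10] <- TRUE; flags_a[41:90] <- TRUE
  flags_b <- flags_a
  flags_b[11] <- TRUE          # one more hit in the chr1 window ...
  flags_b[41] <- FALSE         # ... compensated elsewhere: rate unchanged
  pa <- window_scan(catalog, flags_a)$p_value[1]
  pb <- window_scan(catalog, flags_b)$p_value[1]
  expect_lt(pb, pa)
})

test_that("merge_regions unions overlapping/abutting significant windows and nothing else", {
  expect_equal(nrow(merge_regions(
    data.frame(chrom = "chr1", start = 0, end = 1e6, gene_count = 10L,
               hit_count = 0L, p_value = 1, significant = FALSE))), 0L)
  two <- data.frame(chrom = "chr1", start = c(0, 5e5),
                    end = c(1e6, 1.5e6), gene_count = 10L,
                    hit_count = 5L, p_value = c(1e-4, 1e-6),
                    significant = TRUE)
  merged <- merge_regions(two)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 0)
  expect_equal(merged$end, 1.5e6)
  expect_equal(merged$min_p, 1e-6)
})

test_that("merge_regions agrees with a brute-force union oracle on random patterns", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- 30
      win <- data.frame(
        chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
        start = sample(0:19, n, replace = TRUE) * 5e5
      )
      win$end <- win$start + 1e6
      win$gene_count <- 10L; win$hit_count <- 1L
      win$p_value <- runif(n); win$significant <- runif(n) < 0.4
      win <- win[!duplicated(win[c("chrom", "start")]), ]
      got <- merge_regions(win)
      # oracle: mark covered base-pair bins (5e5 resolution), read off runs
      sig <- win[win$significant, ]
      expected <- list()
      for (ch in sort(unique(sig$chrom))) {
        covered <- rep(FALSE, 42)
        for (i in which(sig$chrom == ch)) {
          bins <- (sig$start[i] / 5e5):(sig$end[i] / 5e5 - 1)
          covered[bins + 1] <- TRUE
        }
        r <- rle(covered)
        ends <- cumsum(r$lengths)
        for (j in which(r$values)) {
          expected[[length(expected) + 1]] <-
            data.frame(chrom = ch, start = (ends[j] - r$lengths[j]) * 5e5,
                       end = ends[j] * 5e5)
        }
      }
      expected <- if (length(expected)) do.call(rbind, expected) else
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0))
      expect_equal(got[c("chrom", "start", "end")], expected,
                   ignore_attr = TRUE)
    }
  })
})

test_that("permutation null is consistent with the binomial default on a planted fixture", {
  cfg <- sim_config(seed = 23, n_chromosomes = 2,
                    chromosome_length_bp = 5e6, n_genes = 600,
                    background_deg_rate = 0.02,
                    hotspots = {
                      h <- qtl_intervals("h", "chr1", 1e6, 2e6)
                      h$elevated_deg_rate <- 0.5
                      h
                    })
  sim <- simulate_expression(cfg)
  calls <- call_degs(sim$expression, sim$samples,
                     c("BIL1_plusQTL", "BIL1_minusQTL"), "root")
  wb <- window_scan(sim$catalog, calls)
  set.seed(1)
  wp <- window_scan(sim$catalog, calls, method = "permutation",
                    n_perm = 500)
  hot <- wb$chrom == "chr1" & wb$start >= 5e5 & wb$start <= 1.5e6
  expect_true(any(wb$significant[hot]))
  expect_true(any(wp$significant[hot]))
  expect_gt(cor(-log10(wb$p_value), -log10(pmax(wp$p_value, 1e-4))), 0.7)
})

test_that("chip_polymorphic_regions recovers planted blocks and only them on a default-geometry fixture", {
  cfg <- sim_config(seed = 37, n_chromosomes = 12,
                    chromosome_length_bp = 20e6, n_genes = 8000)
  blocks <- cfg$polymorphic_blocks   # chr2/chr4 blocks fit a 20 Mb genome
  expect_gte(nrow(blocks), 2L)
  hyb <- simulate_hybridization(cfg)
  calls <- call_hybridization_polymorphisms(
    hyb$intensity, hyb$samples, c("BIL1_plusQTL", "BIL1_minusQTL"))
  regions <- chip_polymorphic_regions(calls, hyb$probes)
  hits <- function(region_row, iv) {
    region_row$chrom == iv$chrom & region_row$start < iv$end &
      region_row$end > iv$start
  }
  for (i in seq_len(nrow(blocks))) {
    n_hit <- sum(vapply(seq_len(nrow(regions)), function(r) {
      hits(regions[r, ], blocks[i, ])
    }, TRUE))
    expect_equal(n_hit, 1L)
  }
  stray <- vapply(seq_len(nrow(regions)), function(r) {
    !any(vapply(seq_len(nrow(blocks)), function(i) {
      hits(regions[r, ], blocks[i, ])
    }, TRUE))
  }, TRUE)
  expect_false(any(stray))
  expect_equal(nrow(chip_polymorphic_regions(calls[0, ], hyb$probes[0, ])),
               0L)
})

test_that("union_regions counts distinct regions across tissues", {
  r1 <- data.frame(chrom = "chr1", start = 0, end = 1e6,
                   n_windows = 1L, min_p = 1e-4)
  r2 <- data.frame(chrom = c("chr1", "chr2"), start = c(5e5, 0),
                   end = c(1.5e6, 1e6), n_windows = 1L, min_p = 1e-5)
  u <- union_regions(list(root = r1, leaf = r2))
  expect_equal(nrow(u), 2L)
  expect_equal(u$end[u$chrom == "chr1"], 1.5e6)
})
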