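# Shared fixture builders and independent oracles.

# random catalog over a compact genome, built directly (not via the
# package's simulator) so reader/writer and interval tests have an
# independent construction path
random_catalog <- function(n = 100, n_chrom = 3, len = 1e6, seed = 42) {
  withr::with_seed(seed, {
    chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
    start <- sort(sample.int(len - 1000, n))
    gene_catalog(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = chrom, start = start,
      end = start + sample(100:900, n, replace = TRUE)
    )
  })
}

# enumeration oracle for the hypergeometric 2x2 test, written from the
# definition with choose() only
enum_fisher_p <- function(a, b, c, d, sided = "greater") {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  if (sided == "greater") {
    sum(prob[support >= a])
  } else {
    p_obs <- prob[support == a]
    sum(prob[prob <= p_obs * (1 + 1e-7)])
  }
}

# closed-form Welch t on two vectors, written independently of
# welch_t_rows
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# small mapping config helper
small_map_config <- function(seed, planted = NULL, n = 200,
                             n_chrom = 3, len = 10.5e6,
                             spacing = 1e6) {
  if (is.null(planted)) {
    planted <- qtl_intervals(character(0), character(0), numeric(0),
                             numeric(0))
    planted$r_squared <- numeric(0)
  }
  sim_config(
    seed = seed, n_chromosomes = n_chrom, chromosome_length_bp = len,
    n_genes = 50,
    mapping_pop = list(planted_qtl = planted, n_individuals = n,
                       marker_spacing_bp = spacing)
  )
}
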