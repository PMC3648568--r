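#' Simulation configuration for the convergent-analysis pipeline
#'
#' Builds the single configuration object consumed by all generators
#' ([simulate_expression()], [simulate_hybridization()],
#' [simulate_mapping_population()], [make_trial_table()]).  The defaults
#' emulate a rice BIL (backcross inbred line) study design: a ~480 Mb
#' genome of 12 chromosomes carrying ~40k positioned genes, two
#' +QTL/−QTL BIL pairs profiled in three tissues (root, leaf, panicle)
#' under two water-stress levels (FTSW 0.5 and 0.2), four planted
#' polymorphic/QTL regions on chromosomes 2, 4, 9 and 10 (see
#' [default_qtl_intervals()]), and a BC4F3-style mapping population of
#' 450 individuals genotyped at 500 kb marker spacing.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   `(config, seed)`.
#' @param n_chromosomes,chromosome_length_bp Genome geometry. Chromosome
#'   lengths are uniform (only relative positions matter downstream).
#' @param n_genes Number of positioned genes drawn uniformly over the
#'   genome.
#' @param background_deg_rate Probability that a gene outside any hotspot
#'   is a planted DEG for a given (BIL pair, tissue).
#' @param hotspots Interval table ([qtl_intervals()]) with an extra
#'   `elevated_deg_rate` column; genes inside (midpoint rule) are planted
#'   DEGs at the elevated rate. Default: the four canonical QTL regions
#'   at ten times the background rate.
#' @param n_replicates Array replicates per (line, tissue, stress).
#' @param expression_noise_sd Gaussian noise sd on the log2 expression
#'   scale.
#' @param deg_effect_log2 Absolute planted log2 expression difference
#'   between +QTL and −QTL lines (sign drawn at random per planted DEG).
#' @param probe_density_per_gene Genomic-hybridization probes per gene.
#' @param hyb_noise_sd Gaussian noise sd of log2 hybridization intensity.
#' @param hyb_shift_sd_multiple Planted intensity shift inside
#'   polymorphic blocks, in units of `hyb_noise_sd`.
#' @param hyb_replicates Hybridization replicates per line.
#' @param polymorphic_blocks Interval table of planted polymorphic
#'   blocks (sequence divergence between the BIL pair).
#' @param mapping_pop List with `n_individuals`, `marker_spacing_bp`,
#'   `planted_qtl` (interval table with an `r_squared` column),
#'   `error_variance` (residual phenotype variance, (kg/ha)^2),
#'   `phenotype_mean` (kg/ha), `background_donor_freq` (donor homozygote
#'   frequency at loci outside segregating QTL blocks; BC4-derived
#'   expectation 1/16) and `cm_per_mb` (Haldane map scale, default 4).
#' @param trial List with `n_sites`, `n_entries`, `check_entry`,
#'   `entry_effects` (named kg/ha advantages, default all zero),
#'   `site_sd` and `noise_sd` for [make_trial_table()]'s simulated mode.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 12L,
                       chromosome_length_bp = 40e6,
                       n_genes = 40000L,
                       background_deg_rate = 0.01,
                       hotspots = NULL,
                       n_replicates = 3L,
                       expression_noise_sd = 0.5,
                       deg_effect_log2 = 2.5,
                       probe_density_per_gene = 1L,
                       hyb_noise_sd = 0.2,
                       hyb_shift_sd_multiple = 5,
                       hyb_replicates = 4L,
                       polymorphic_blocks = default_qtl_intervals(),
                       mapping_pop = list(),
                       trial = list()) {
  chroms <- paste0("chr", seq_len(n_chromosomes))
  # defaulted interval tables are restricted to the simulated genome;
  # user-supplied ones are validated strictly
  clip_default <- function(iv) {
    iv[iv$chrom %in% chroms & iv$end <= chromosome_length_bp, ,
       drop = FALSE]
  }
  if (is.null(hotspots)) {
    hotspots <- clip_default(default_qtl_intervals())
    hotspots$elevated_deg_rate <- rep(10 * background_deg_rate,
                                      nrow(hotspots))
  }
  if (missing(polymorphic_blocks)) {
    polymorphic_blocks <- clip_default(polymorphic_blocks)
  }
  mp_default <- list(
    n_individuals = 450L,
    marker_spacing_bp = 5e5,
    planted_qtl = cbind(default_qtl_intervals(),
                        r_squared = c(0.091, 0.112, 0.130, 0.170)),
    error_variance = 360000,
    phenotype_mean = 2000,
    background_donor_freq = 1 / 16,
    cm_per_mb = 4
  )
  if (is.null(mapping_pop$planted_qtl)) {
    mp_default$planted_qtl <- clip_default(mp_default$planted_qtl)
  }
  # shallow merge: components are replaced wholesale (modifyList would
  # recurse into data.frame components and recycle their columns)
  mp_default[names(mapping_pop)] <- mapping_pop
  mapping_pop <- mp_default
  trial_default <- list(
    n_sites = 7L,
    n_entries = 4L,
    check_entry = "IR64",
    entry_effects = NULL,
    site_sd = 600,
    noise_sd = 150
  )
  trial_default[names(trial)] <- trial
  trial <- trial_default
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = chromosome_length_bp,
    n_genes = as.integer(n_genes),
    background_deg_rate = background_deg_rate,
    hotspots = hotspots,
    n_replicates = as.integer(n_replicates),
    expression_noise_sd = expression_noise_sd,
    deg_effect_log2 = deg_effect_log2,
    probe_density_per_gene = as.integer(probe_density_per_gene),
    hyb_noise_sd = hyb_noise_sd,
    hyb_shift_sd_multiple = hyb_shift_sd_multiple,
    hyb_replicates = as.integer(hyb_replicates),
    polymorphic_blocks = polymorphic_blocks,
    mapping_pop = mapping_pop,
    trial = trial
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rate_in_01 <- function(x) all(x >= 0 & x <= 1)
  if (!rate_in_01(cfg$background_deg_rate)) {
    stop("background_deg_rate must be in [0, 1]")
  }
  if (cfg$expression_noise_sd <= 0 || cfg$hyb_noise_sd <= 0) {
    stop("noise sd values must be positive")
  }
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  check_on_genome <- function(iv, what) {
    if (is.null(iv) || nrow(iv) == 0L) return(invisible())
    if (!all(iv$chrom %in% chroms) ||
        any(iv$end > cfg$chromosome_length_bp) || any(iv$start < 0)) {
      stop(what, " interval lies off the simulated genome")
    }
  }
  check_on_genome(cfg$hotspots, "hotspot")
  check_on_genome(cfg$polymorphic_blocks, "polymorphic block")
  if (!is.null(cfg$hotspots) && nrow(cfg$hotspots) &&
      !rate_in_01(cfg$hotspots$elevated_deg_rate)) {
    stop("elevated_deg_rate must be in [0, 1]")
  }
  pq <- cfg$mapping_pop$planted_qtl
  if (!is.null(pq) && nrow(pq)) {
    check_on_genome(pq, "planted QTL")
    if (!rate_in_01(pq$r_squared)) stop("r_squared must be in [0, 1]")
    if (sum(pq$r_squared) >= 1) {
      stop("planted QTL r_squared values sum to >= 1")
    }
  }
  if (cfg$mapping_pop$error_variance <= 0) {
    stop("error_variance must be positive")
  }
  invisible(cfg)
}

#' Simulate a positioned gene catalog
#'
#' Gene starts are uniform over each chromosome with log-normal gene
#' lengths (median ~2.5 kb). Deterministic under `config$seed`; the other
#' generators draw the same catalog internally, so catalogs, expression
#' matrices and probe sets from one config are mutually consistent.
#'
#' @param config A [sim_config()].
#' @return A [gene_catalog].
#' @export
simulate_gene_catalog <- function(config) {
  with_sim_seed(config$seed, sim_catalog_impl(config))
}

sim_catalog_impl <- function(config) {
  per_chrom <- table(factor(
    sample.int(config$n_chromosomes, config$n_genes, replace = TRUE),
    levels = seq_len(config$n_chromosomes)
  ))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chrom)
  start <- floor(stats::runif(config$n_genes, 0,
                              config$chromosome_length_bp - 10000))
  len <- pmax(200, round(stats::rlnorm(config$n_genes,
                                       meanlog = log(2500), sdlog = 0.6)))
  end <- pmin(start + len, config$chromosome_length_bp)
  ord <- order(chrom, start)
  gene_catalog(
    gene_id = sprintf("gene_%05d", seq_len(config$n_genes)),
    chrom = chrom[ord], start = start[ord], end = end[ord]
  )
}

with_sim_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

sample_sheet <- function(config) {
  lines <- data.frame(
    line_id = c("BIL1_plusQTL", "BIL1_minusQTL",
                "BIL2_plusQTL", "BIL2_minusQTL"),
    pair = c("pair1", "pair1", "pair2", "pair2"),
    qtl_class = c("plusQTL", "minusQTL", "plusQTL", "minusQTL"),
    stringsAsFactors = FALSE
  )
  meta <- expand.grid(
    replicate = seq_len(config$n_replicates),
    stress = c("FTSW_0.5", "FTSW_0.2"),
    tissue = c("root", "leaf", "panicle"),
    line_id = lines$line_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  meta <- merge(meta, lines, by = "line_id", sort = FALSE)
  meta$sample_id <- sprintf("%s.%s.%s.r%d", meta$line_id, meta$tissue,
                            meta$stress, meta$replicate)
  meta[, c("sample_id", "line_id", "pair", "qtl_class", "tissue",
           "stress", "replicate")]
}

deg_rate_by_gene <- function(catalog, config) {
  rate <- rep(config$background_deg_rate, nrow(catalog))
  hs <- config$hotspots
  if (!is.null(hs) && nrow(hs)) {
    mid <- gene_midpoint(catalog)
    for (i in seq_len(nrow(hs))) {
      inside <- catalog$chrom == hs$chrom[i] &
        mid >= hs$start[i] & mid < hs$end[i]
      rate[inside] <- hs$elevated_deg_rate[i]
    }
  }
  rate
}

#' Simulate a BIL-pair expression experiment
#'
#' Generates the gene catalog, a genes x samples log2 expression matrix
#' for two +QTL/−QTL BIL pairs x three tissues x two stress levels x
#' `n_replicates`, the sample sheet, and the ground-truth table of
#' planted DEGs.  Per-gene expression is baseline + line effect (nonzero
#' only for planted DEGs, applied to the +QTL line of the pair in the
#' affected tissue at both stress levels) + Gaussian noise.
#'
#' @param config A [sim_config()].
#' @param planted Optional explicit truth table (`gene_id`, `pair`,
#'   `tissue`) overriding the rate-based draw; an `effect_log2` column is
#'   honoured if present.
#' @return A list with elements `catalog`, `expression` (matrix, rownames
#'   = gene ids, colnames = sample ids), `samples` (sample sheet) and
#'   `truth` (planted DEGs: `gene_id`, `pair`, `tissue`, `effect_log2`).
#' @export
simulate_expression <- function(config, planted = NULL) {
  with_sim_seed(config$seed, {
    catalog <- sim_catalog_impl(config)
    samples <- sample_sheet(config)
    if (is.null(planted)) {
      rate <- deg_rate_by_gene(catalog, config)
      cells <- expand.grid(pair = c("pair1", "pair2"),
                           tissue = c("root", "leaf", "panicle"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      truth_list <- lapply(seq_len(nrow(cells)), function(i) {
        hit <- stats::runif(nrow(catalog)) < rate
        if (!any(hit)) return(NULL)
        data.frame(gene_id = catalog$gene_id[hit],
                   pair = cells$pair[i], tissue = cells$tissue[i],
                   stringsAsFactors = FALSE)
      })
      truth <- do.call(rbind, truth_list)
      if (is.null(truth)) {
        truth <- data.frame(gene_id = character(0), pair = character(0),
                            tissue = character(0))
      }
    } else {
      truth <- as.data.frame(planted, stringsAsFactors = FALSE)
      if (!all(truth$gene_id %in% catalog$gene_id)) {
        stop("planted truth table names genes absent from the catalog")
      }
    }
    if (nrow(truth) && is.null(truth$effect_log2)) {
      truth$effect_log2 <- config$deg_effect_log2 *
        sample(c(-1, 1), nrow(truth), replace = TRUE)
    }
    baseline <- stats::rnorm(nrow(catalog), mean = 8, sd = 1.5)
    expr <- matrix(
      baseline + stats::rnorm(nrow(catalog) * nrow(samples), 0,
                              config$expression_noise_sd),
      nrow = nrow(catalog), ncol = nrow(samples),
      dimnames = list(catalog$gene_id, samples$sample_id)
    )
    if (nrow(truth)) {
      gi <- match(truth$gene_id, catalog$gene_id)
      for (k in seq_len(nrow(truth))) {
        cols <- samples$pair == truth$pair[k] &
          samples$tissue == truth$tissue[k] &
          samples$qtl_class == "plusQTL"
        expr[gi[k], cols] <- expr[gi[k], cols] + truth$effect_log2[k]
      }
    }
    list(catalog = catalog, expression = expr, samples = samples,
         truth = truth)
  })
}

#' Simulate a genomic-DNA hybridization (genotyping chip) experiment
#'
#' Probes are placed evenly within each gene (`probe_density_per_gene`
#' per gene).  Log2 intensities are baseline + noise; probes whose
#' midpoint falls inside a planted polymorphic block receive a
#' line-specific shift of `hyb_shift_sd_multiple * hyb_noise_sd`
#' (sequence divergence between the +QTL and −QTL line of the pair;
#' shift direction fixed per block).
#'
#' @param config A [sim_config()].
#' @return A list with `probes` (a [gene_catalog]-style probe catalog),
#'   `intensity` (probes x samples matrix), `samples` (sample sheet:
#'   `sample_id`, `line_id`, `replicate`) and `truth` (probes inside
#'   polymorphic blocks: `probe_id`, `block`).
#' @export
simulate_hybridization <- function(config) {
  with_sim_seed(config$seed, {
    catalog <- sim_catalog_impl(config)
    k <- config$probe_density_per_gene
    rel <- (seq_len(k) - 0.5) / k
    probe_start <- floor(rep(catalog$start, each = k) +
                           rel * (rep(catalog$end - catalog$start, each = k)))
    probes <- gene_catalog(
      gene_id = sprintf("probe_%05d_%02d",
                        rep(seq_len(nrow(catalog)), each = k),
                        rep(seq_len(k), times = nrow(catalog))),
      chrom = rep(catalog$chrom, each = k),
      start = probe_start,
      end = probe_start + 25
    )
    samples <- expand.grid(
      replicate = seq_len(config$hyb_replicates),
      line_id = c("BIL1_plusQTL", "BIL1_minusQTL"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    samples$sample_id <- sprintf("%s.gDNA.r%d", samples$line_id,
                                 samples$replicate)
    samples <- samples[, c("sample_id", "line_id", "replicate")]
    baseline <- stats::rnorm(nrow(probes), mean = 10, sd = 1)
    intens <- matrix(
      baseline + stats::rnorm(nrow(probes) * nrow(samples), 0,
                              config$hyb_noise_sd),
      nrow = nrow(probes), ncol = nrow(samples),
      dimnames = list(probes$gene_id, samples$sample_id)
    )
    blocks <- config$polymorphic_blocks
    truth <- data.frame(probe_id = character(0), block = character(0))
    if (!is.null(blocks) && nrow(blocks)) {
      mid <- gene_midpoint(probes)
      shift_sign <- rep(c(1, -1), length.out = nrow(blocks))
      for (i in seq_len(nrow(blocks))) {
        inside <- probes$chrom == blocks$chrom[i] &
          mid >= blocks$start[i] & mid < blocks$end[i]
        if (!any(inside)) next
        shift <- shift_sign[i] * config$hyb_shift_sd_multiple *
          config$hyb_noise_sd
        minus_cols <- samples$line_id == "BIL1_minusQTL"
        intens[inside, minus_cols] <- intens[inside, minus_cols] + shift
        truth <- rbind(truth, data.frame(
          probe_id = probes$gene_id[inside], block = blocks$name[i],
          stringsAsFactors = FALSE
        ))
      }
    }
    list(probes = probes, intensity = intens, samples = samples,
         truth = truth)
  })
}

haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' Simulate a BC4F3-style mapping population
#'
#' Genotypes are simulated as a donor/recurrent two-state Markov chain
#' along each chromosome per individual (Haldane map function at
#' `cm_per_mb`), doubled to homozygote codes \{0, 2\} — backcross-derived
#' inbreds are modelled as fixed, with residual heterozygosity collapsed
#' to the minor homozygote class.  The marginal donor frequency is 0.5
#' at markers inside planted QTL intervals (the segregating
#' introgressions) and `background_donor_freq` (default 1/16) elsewhere.
#'
#' The phenotype is the sum of planted additive QTL effects plus normal
#' error, in kg/ha.  Effects are calibrated against the realized sample
#' moments (error residualised against the planted-QTL marker genotypes,
#' coefficients solved from their sample correlation matrix), so the
#' marginal sample R^2 of each planted QTL at its marker equals the
#' requested value exactly.
#'
#' @param config A [sim_config()].
#' @return A list with `map` (marker map: `marker_id`, `chrom`,
#'   `position_bp`, `position_cM`), `geno` (individuals x markers code
#'   matrix), `pheno` (numeric vector, kg/ha) and `truth` (per planted
#'   QTL: `name`, `chrom`, `position_bp`, `marker_id`, `r_squared`,
#'   `additive_kg_ha`).
#' @export
simulate_mapping_population <- function(config) {
  mp <- config$mapping_pop
  with_sim_seed(config$seed, {
    spacing <- mp$marker_spacing_bp
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    map_list <- lapply(chroms, function(ch) {
      pos <- seq(0, config$chromosome_length_bp - 1, by = spacing)
      data.frame(
        marker_id = sprintf("%s_M%03d", ch, seq_along(pos)),
        chrom = ch, position_bp = pos,
        position_cM = pos / 1e6 * mp$cm_per_mb,
        stringsAsFactors = FALSE
      )
    })
    map <- do.call(rbind, map_list)
    rownames(map) <- NULL

    pq <- mp$planted_qtl
    seg <- if (!is.null(pq) && nrow(pq)) pq else NULL
    pi_marg <- rep(mp$background_donor_freq, nrow(map))
    if (!is.null(seg)) {
      for (i in seq_len(nrow(seg))) {
        inside <- map$chrom == seg$chrom[i] &
          map$position_bp >= seg$start[i] & map$position_bp < seg$end[i]
        pi_marg[inside] <- 0.5
      }
    }

    n <- mp$n_individuals
    geno <- matrix(NA_real_, nrow = n, ncol = nrow(map),
                   dimnames = list(sprintf("ind_%03d", seq_len(n)),
                                   map$marker_id))
    for (ch in chroms) {
      idx <- which(map$chrom == ch)
      d <- stats::runif(n) < pi_marg[idx[1L]]
      geno[, idx[1L]] <- 2 * d
      if (length(idx) > 1L) {
        r <- haldane_r(diff(map$position_cM[idx]))
        for (j in seq_along(r)) {
          k0 <- idx[j]; k1 <- idx[j + 1L]
          p <- pi_marg[k1] + (d - pi_marg[k0]) * (1 - 2 * r[j])
          p <- pmin(pmax(p, 0), 1)
          d <- stats::runif(n) < p
          geno[, k1] <- 2 * d
        }
      }
    }

    if (is.null(seg)) {
      pheno <- mp$phenotype_mean +
        sqrt(mp$error_variance) * stats::rnorm(n)
      truth <- data.frame(name = character(0), chrom = character(0),
                          position_bp = numeric(0), marker_id = character(0),
                          r_squared = numeric(0), additive_kg_ha = numeric(0))
      return(list(map = map, geno = geno, pheno = pheno, truth = truth))
    }

    qtl_pos <- floor((seg$start + seg$end) / 2)
    qm <- vapply(seq_len(nrow(seg)), function(i) {
      cand <- which(map$chrom == seg$chrom[i])
      if (!length(cand)) stop("no markers span planted QTL ", seg$name[i])
      cand[which.min(abs(map$position_bp[cand] - qtl_pos[i]))]
    }, integer(1))
    G <- geno[, qm, drop = FALSE]
    sds <- apply(G, 2, stats::sd)
    if (any(sds == 0)) {
      stop("planted QTL marker is monomorphic in the simulated sample; ",
           "increase n_individuals")
    }
    U <- scale(G)            # sample-standardized QTL marker codes
    C <- stats::cor(G)
    cvec <- sqrt(seg$r_squared)
    expl <- drop(crossprod(cvec, solve(C, cvec)))
    if (expl >= 1) stop("planted QTL r_squared values jointly infeasible")
    beta <- solve(C, cvec)
    e0 <- stats::rnorm(n)
    e_perp <- stats::residuals(stats::lm.fit(cbind(1, U), e0))
    e_unit <- e_perp / stats::sd(e_perp)
    z <- drop(U %*% beta) + sqrt(1 - expl) * e_unit
    scale_kg <- sqrt(mp$error_variance / (1 - expl))
    pheno <- mp$phenotype_mean + scale_kg * z
    truth <- data.frame(
      name = seg$name, chrom = seg$chrom, position_bp = qtl_pos,
      marker_id = map$marker_id[qm], r_squared = seg$r_squared,
      additive_kg_ha = scale_kg * beta / sds,
      stringsAsFactors = FALSE
    )
    list(map = map, geno = geno, pheno = pheno, truth = truth)
  })
}

#' Multi-environment trial yield tables
#'
#' Returns a long-format trial table with columns `entry`, `site`,
#' `regime` (`"non_stress"`/`"stress"`), `yield_kg_ha` and `lsd_kg_ha`
#' (the per-site, per-regime least significant difference, `NA` where
#' unavailable).
#'
#' Two packaged fixtures transcribe published multi-environment trial
#' results for IR64 qDTY-introgression lines cell by cell:
#' `"table5"` — the IRRI dry-season screens (seasons DS10/DS11 as
#' `site`) of fourteen QTL lines plus the IR64 check; `"table6"` — the
#' three best lines plus IR64 at seven target sites in Bangladesh, Nepal
#' and India.  `"simulated"` draws site x entry yields with configurable
#' entry effects (zero by default) for null testing.
#'
#' @param source `"table5"`, `"table6"` or `"simulated"`.
#' @param config A [sim_config()]; used (and required) only for
#'   `"simulated"`.
#' @return A trial-table `data.frame`.
#' @export
make_trial_table <- function(source = c("table5", "table6", "simulated"),
                             config = NULL) {
  source <- match.arg(source)
  if (source %in% c("table5", "table6")) {
    path <- system.file("extdata", paste0(source, "_yield.tsv"),
                        package = "qtlconverge", mustWork = TRUE)
    tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
    tbl$yield_kg_ha <- as.numeric(tbl$yield_kg_ha)
    tbl$lsd_kg_ha <- suppressWarnings(as.numeric(tbl$lsd_kg_ha))
    return(tbl)
  }
  if (is.null(config)) stop("simulated trial table requires a config")
  tr <- config$trial
  with_sim_seed(config$seed, {
    entries <- c(tr$check_entry,
                 sprintf("QTL_line_%d", seq_len(tr$n_entries - 1L)))
    effects <- stats::setNames(rep(0, length(entries)), entries)
    if (!is.null(tr$entry_effects)) {
      effects[names(tr$entry_effects)] <- tr$entry_effects
    }
    grid <- expand.grid(
      entry = entries,
      site = sprintf("site_%d", seq_len(tr$n_sites)),
      regime = c("non_stress", "stress"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    site_eff <- stats::setNames(
      stats::rnorm(tr$n_sites, 0, tr$site_sd),
      sprintf("site_%d", seq_len(tr$n_sites))
    )
    base <- ifelse(grid$regime == "stress", 1500, 4500)
    adv <- ifelse(grid$regime == "stress", effects[grid$entry], 0)
    grid$yield_kg_ha <- round(base + site_eff[grid$site] + adv +
                                stats::rnorm(nrow(grid), 0, tr$noise_sd))
    grid$lsd_kg_ha <- round(1.96 * sqrt(2) * tr$noise_sd)
    grid
  })
}
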