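#' Genotype and marker-map I/O
#'
#' Genotype TSV: rows are markers, columns individuals, codes `A`
#' (recurrent homozygote, 0), `H` (heterozygote, 1), `B` (donor
#' homozygote, 2), `-` (missing).  Marker-map TSV: columns `marker_id`,
#' `chrom`, `position_bp`, `position_cM`.
#'
#' @param path File path.
#' @param geno Individuals x markers numeric code matrix.
#' @param map Marker map `data.frame`.
#' @return `read_genotypes`: individuals x markers numeric matrix
#'   (0/1/2/NA); `read_marker_map`: the map `data.frame`; writers return
#'   `path` invisibly.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  markers <- df[[1L]]
  codes <- as.matrix(df[, -1L, drop = FALSE])
  num <- matrix(NA_real_, nrow = nrow(codes), ncol = ncol(codes))
  num[codes == "A"] <- 0
  num[codes == "H"] <- 1
  num[codes == "B"] <- 2
  bad <- !(codes %in% c("A", "H", "B", "-", NA))
  if (any(bad)) {
    stop("invalid genotype code(s): ",
         paste(unique(codes[bad]), collapse = ", "))
  }
  t(structure(num, dimnames = list(markers, colnames(codes))))
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(geno, path) {
  codes <- matrix("-", nrow = ncol(geno), ncol = nrow(geno),
                  dimnames = list(colnames(geno), rownames(geno)))
  gt <- t(geno)
  codes[!is.na(gt) & gt == 0] <- "A"
  codes[!is.na(gt) & gt == 1] <- "H"
  codes[!is.na(gt) & gt == 2] <- "B"
  out <- data.frame(marker_id = rownames(codes), codes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_genotypes
#' @export
read_marker_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "position_bp", "position_cM")
  if (!all(need %in% names(map))) {
    stop("marker map must have columns ", paste(need, collapse = ", "))
  }
  map
}

check_scan_inputs <- function(geno, pheno, map) {
  if (!all(map$marker_id %in% colnames(geno))) {
    stop("genotype matrix is missing markers listed in the map")
  }
  if (length(pheno) != nrow(geno)) {
    stop("phenotype length does not match individual count")
  }
  ok <- is.na(geno) | geno %in% c(0, 1, 2)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or missing")
  by_chrom <- split(map$position_cM, map$chrom)
  if (any(vapply(by_chrom, function(p) any(diff(p) <= 0), TRUE))) {
    stop("marker positions must be strictly increasing per chromosome")
  }
  invisible(TRUE)
}

lod_floor <- 1e-12  # RSS1 floor relative to RSS0 caps LOD in perfect fits

lod_from_r2 <- function(r2, n) {
  r2 <- pmin(pmax(r2, 0), 1 - lod_floor)
  -(n / 2) * log10(1 - r2)
}

#' Single-marker QTL scan
#'
#' Regresses the phenotype on the additive genotype code at each marker
#' separately, with pairwise deletion of missing genotypes.
#' `LOD = (n/2) log10(RSS0/RSS1)`, `R^2 = 1 - RSS1/RSS0`; `RSS1` is
#' floored at `1e-12 * RSS0` to cap the LOD in degenerate perfect fits.
#' The additive effect is the conventional half difference between
#' homozygote class means (donor minus recurrent, phenotype units).
#' Monomorphic markers are recorded with LOD 0 and a warning.
#'
#' @param geno Individuals x markers code matrix (0/1/2/NA), columns
#'   named by marker.
#' @param pheno Numeric phenotype vector.
#' @param map Marker map (`marker_id`, `chrom`, `position_bp`,
#'   `position_cM`), strictly increasing positions per chromosome.
#' @return A `qtl_scan` `data.frame`: `marker_id`, `chrom`,
#'   `position_bp`, `position_cM`, `n`, `LOD`, `r_squared`,
#'   `additive_effect`, `F_value`.
#' @export
single_marker_scan <- function(geno, pheno, map) {
  check_scan_inputs(geno, pheno, map)
  res <- lapply(seq_len(nrow(map)), function(i) {
    g <- geno[, map$marker_id[i]]
    use <- !is.na(g) & !is.na(pheno)
    g <- g[use]; y <- pheno[use]
    n <- length(y)
    if (n < 3L || stats::sd(g) == 0 || stats::sd(y) == 0) {
      return(data.frame(n = n, LOD = 0, r_squared = 0,
                        additive_effect = NA_real_, F_value = 0,
                        monomorphic = stats::sd(g) == 0))
    }
    r2 <- stats::cor(g, y)^2
    add <- if (any(g == 0) && any(g == 2)) {
      (mean(y[g == 2]) - mean(y[g == 0])) / 2
    } else {
      NA_real_
    }
    r2c <- min(r2, 1 - lod_floor)
    data.frame(n = n, LOD = lod_from_r2(r2, n), r_squared = r2,
               additive_effect = add,
               F_value = r2c / (1 - r2c) * (n - 2),
               monomorphic = FALSE)
  })
  res <- do.call(rbind, res)
  if (any(res$monomorphic)) {
    warning(sum(res$monomorphic), " monomorphic marker(s); LOD set to 0")
  }
  out <- cbind(map[, c("marker_id", "chrom", "position_bp",
                       "position_cM")],
               res[, c("n", "LOD", "r_squared", "additive_effect",
                       "F_value")])
  rownames(out) <- NULL
  class(out) <- c("qtl_scan", "data.frame")
  attr(out, "scan_type") <- "single_marker"
  out
}

# expected donor-allele dose (0..1) at a query cM position given flanking
# marker doses under a two-state Haldane chain; dL/dR are n-vectors in
# [0,1], NA allowed (flank unavailable)
expected_dose <- function(dL, dR, rL, rR) {
  fL <- if (is.null(dL)) NULL else dL * (1 - rL) + (1 - dL) * rL
  fR <- if (is.null(dR)) NULL else dR * (1 - rR) + (1 - dR) * rR
  if (is.null(fL)) return(fR)
  if (is.null(fR)) return(fL)
  num <- fL * fR
  num / (num + (1 - fL) * (1 - fR))
}

# fill missing marker doses per individual from the nearest non-missing
# marker on the chromosome (marginal 0.5 if the whole chromosome is
# missing); doses on the 0..1 scale
fill_doses <- function(D) {
  miss <- is.na(D)
  if (!any(miss)) return(D)
  for (i in which(rowSums(miss) > 0)) {
    d <- D[i, ]
    obs <- which(!is.na(d))
    if (!length(obs)) {
      D[i, ] <- 0.5
      next
    }
    for (j in which(is.na(d))) {
      D[i, j] <- d[obs[which.min(abs(obs - j))]]
    }
  }
  D
}

scan_grid <- function(map_ch, step_cM) {
  pos <- map_ch$position_cM
  sort(unique(c(pos, seq(min(pos), max(pos), by = step_cM))))
}

# residual sum of squares of y on [1, X] via QR; X may have 0 columns
rss_qr <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  sum(stats::residuals(fit)^2)
}

hk_scan_engine <- function(geno, pheno, map, step_cM, cofactor_ids,
                           window_cM) {
  n <- length(pheno)
  degenerate_y <- stats::sd(pheno, na.rm = TRUE) == 0
  cof_pos <- map[match(cofactor_ids, map$marker_id), , drop = FALSE]
  cof_mat <- geno[, cofactor_ids, drop = FALSE]
  if (ncol(cof_mat)) {
    # mean-impute missing cofactor genotypes
    for (j in seq_len(ncol(cof_mat))) {
      nas <- is.na(cof_mat[, j])
      if (any(nas)) cof_mat[nas, j] <- mean(cof_mat[, j], na.rm = TRUE)
    }
  }
  out <- list()
  for (ch in unique(map$chrom)) {
    map_ch <- map[map$chrom == ch, , drop = FALSE]
    D <- fill_doses(geno[, map_ch$marker_id, drop = FALSE] / 2)
    grid <- scan_grid(map_ch, step_cM)
    mpos <- map_ch$position_cM
    bp <- stats::approx(mpos, map_ch$position_bp, xout = grid,
                        rule = 2)$y
    lod <- r2 <- add <- numeric(length(grid))
    nvec <- integer(length(grid))
    for (gi in seq_along(grid)) {
      q <- grid[gi]
      hit <- match(TRUE, abs(mpos - q) < 1e-9)
      x <- if (!is.na(hit)) {
        2 * D[, hit]
      } else {
        left <- max(which(mpos < q))
        right <- min(which(mpos > q))
        2 * expected_dose(D[, left], D[, right],
                          haldane_r(q - mpos[left]),
                          haldane_r(mpos[right] - q))
      }
      keep_cof <- if (ncol(cof_mat)) {
        cof_pos$chrom != ch | abs(cof_pos$position_cM - q) > window_cM
      } else {
        logical(0)
      }
      Xc <- cof_mat[, keep_cof, drop = FALSE]
      use <- !is.na(pheno)
      y <- pheno[use]
      rss0 <- rss_qr(Xc[use, , drop = FALSE], y)
      rss1 <- rss_qr(cbind(Xc, x)[use, , drop = FALSE], y)
      rss1 <- max(rss1, lod_floor * rss0)
      nvec[gi] <- length(y)
      if (degenerate_y || rss0 <= 0 || stats::sd(x[use]) == 0) {
        lod[gi] <- 0; r2[gi] <- 0; add[gi] <- NA_real_
      } else {
        lod[gi] <- (length(y) / 2) * log10(rss0 / rss1)
        r2[gi] <- 1 - rss1 / rss0
        xr <- x[use]
        add[gi] <- stats::cov(xr, y) / stats::var(xr)
      }
    }
    out[[ch]] <- data.frame(
      chrom = ch, position_cM = grid, position_bp = bp, n = nvec,
      LOD = lod, r_squared = r2, additive_effect = add,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("qtl_scan", "data.frame")
  res
}

#' Interval mapping by Haley-Knott regression
#'
#' Evaluates a LOD profile on a cM grid (observed marker positions plus
#' a `step_cM` lattice).  At pseudomarkers, the expected donor dose is
#' computed from the flanking markers under Haldane's map function, and
#' the phenotype is regressed on the expected additive code
#' (Haley-Knott approximation).  Missing marker genotypes are imputed
#' from the nearest non-missing marker on the chromosome.
#'
#' @inheritParams single_marker_scan
#' @param step_cM Grid step in cM (default 1; must be positive).
#' @return A `qtl_scan` `data.frame` with one row per evaluated
#'   position: `chrom`, `position_cM`, `position_bp`, `n`, `LOD`,
#'   `r_squared`, `additive_effect`.  Use [scan_peaks()] for the
#'   per-chromosome peak table.
#' @export
interval_scan <- function(geno, pheno, map, step_cM = 1) {
  if (step_cM <= 0) stop("step_cM must be positive")
  check_scan_inputs(geno, pheno, map)
  n_per_chrom <- table(map$chrom)
  if (any(n_per_chrom < 2L)) {
    stop("interval mapping needs >= 2 markers per chromosome")
  }
  out <- hk_scan_engine(geno, pheno, map, step_cM,
                        cofactor_ids = character(0), window_cM = 0)
  attr(out, "scan_type") <- "interval"
  out
}

#' Composite interval mapping
#'
#' Interval mapping with forward-selected marker cofactors: up to
#' `n_cofactors` markers are chosen by greedy residual-sum-of-squares
#' reduction and included as covariates, except that cofactors within
#' `window_cM` of the test position (same chromosome) are dropped from
#' the model at that position.  Collinear cofactor candidates are
#' skipped with a warning.  With `n_cofactors = 0` the scan is identical
#' to [interval_scan()].  LOD and R^2 are relative to the
#' cofactors-only model at each position.
#'
#' @inheritParams interval_scan
#' @param n_cofactors Number of marker cofactors (must be < n/10).
#' @param window_cM Exclusion window around the test position (default
#'   10 cM).
#' @return A `qtl_scan` `data.frame`, as [interval_scan()].
#' @export
composite_scan <- function(geno, pheno, map, n_cofactors,
                           step_cM = 1, window_cM = 10) {
  if (step_cM <= 0) stop("step_cM must be positive")
  check_scan_inputs(geno, pheno, map)
  if (n_cofactors >= length(pheno) / 10) {
    stop("n_cofactors must be < n/10")
  }
  cof <- character(0)
  if (n_cofactors > 0) {
    G <- geno[, map$marker_id, drop = FALSE]
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
    }
    use <- !is.na(pheno)
    y <- pheno[use]
    dropped <- 0L
    for (k in seq_len(n_cofactors)) {
      Xc <- G[use, cof, drop = FALSE]
      base_fit <- stats::lm.fit(cbind(1, Xc), y)
      resid_y <- stats::residuals(base_fit)
      best <- NA_character_; best_gain <- 0
      for (cand in setdiff(map$marker_id, cof)) {
        x <- G[use, cand]
        rx <- stats::residuals(stats::lm.fit(cbind(1, Xc), x))
        vx <- sum(rx^2)
        if (vx < 1e-10 * length(y)) next  # collinear with current set
        gain <- sum(rx * resid_y)^2 / vx
        if (gain > best_gain) {
          best <- cand; best_gain <- gain
        }
      }
      if (is.na(best)) {
        dropped <- n_cofactors - length(cof)
        break
      }
      cof <- c(cof, best)
    }
    if (dropped > 0L) {
      warning(dropped, " cofactor slot(s) unfilled: remaining markers ",
              "collinear with the selected set")
    }
  }
  out <- hk_scan_engine(geno, pheno, map, step_cM, cof, window_cM)
  attr(out, "scan_type") <- "composite"
  attr(out, "cofactors") <- cof
  out
}

#' Per-chromosome scan peaks
#'
#' Summarises a `qtl_scan` into one row per chromosome at the LOD
#' maximum (ties broken toward the smaller genomic coordinate), with
#' the flanking observed-marker interval and nearest peak marker,
#' mirroring the conventional QTL-table layout (marker interval, peak
#' marker, LOD, R^2, additive effect).
#'
#' @param scan A `qtl_scan` from any scan function.
#' @param map The marker map used for the scan.
#' @param threshold Optional LOD threshold; peaks below it are dropped.
#' @return A `data.frame` with one row per (retained) chromosome:
#'   `chrom`, `position_cM`, `position_bp`, `marker_interval`,
#'   `peak_marker`, `LOD`, `r_squared`, `additive_effect`.
#' @export
scan_peaks <- function(scan, map, threshold = NULL) {
  rows <- lapply(split(scan, scan$chrom), function(s) {
    i <- which.max(s$LOD)   # which.max takes the first (smaller coord)
    map_ch <- map[map$chrom == s$chrom[1L], , drop = FALSE]
    q <- s$position_cM[i]
    left <- map_ch$marker_id[max(c(1L, which(map_ch$position_cM <= q)))]
    right <- map_ch$marker_id[min(c(nrow(map_ch),
                                    which(map_ch$position_cM >= q)))]
    nearest <- map_ch$marker_id[which.min(abs(map_ch$position_cM - q))]
    data.frame(chrom = s$chrom[1L], position_cM = q,
               position_bp = s$position_bp[i],
               marker_interval = paste(left, right, sep = "-"),
               peak_marker = nearest, LOD = s$LOD[i],
               r_squared = s$r_squared[i],
               additive_effect = s$additive_effect[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(threshold)) {
    out <- out[out$LOD > threshold, , drop = FALSE]
  }
  out
}

#' Empirical genome-wide LOD threshold by phenotype permutation
#'
#' Permutes the phenotype `n_perm` times, records the genome-wide
#' maximum single-marker LOD of each permutation, and returns the
#' empirical `(1 - alpha)` quantile as the threshold order statistic
#' `ceiling((1 - alpha) * (n_perm + 1))`, whose exceedance probability
#' under exchangeability is `(n_perm + 1 - idx) / (n_perm + 1)` (about
#' `alpha`).  Missing genotypes are mean-imputed for the vectorised
#' permutation pass.  Deterministic under `seed`.
#'
#' @inheritParams single_marker_scan
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Genome-wide significance level (default 0.01).
#' @param seed Optional integer seed.
#' @return The threshold LOD (numeric scalar) with the permuted max-LOD
#'   distribution in `attr(, "max_lods")`.
#' @export
permutation_threshold <- function(geno, pheno, map, n_perm = 1000L,
                                  alpha = 0.01, seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  check_scan_inputs(geno, pheno, map)
  X <- geno[, map$marker_id, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  n <- length(pheno)
  run <- function() {
    Xs <- scale(X)
    P <- matrix(0, n, n_perm)
    for (b in seq_len(n_perm)) P[, b] <- pheno[sample.int(n)]
    Ps <- scale(P)
    R <- crossprod(Xs, Ps) / (n - 1)
    max_lods <- apply(lod_from_r2(R^2, n), 2, max)
    idx <- min(n_perm, max(1L, ceiling((1 - alpha) * (n_perm + 1))))
    thr <- sort(max_lods)[idx]
    attr(thr, "max_lods") <- max_lods
    thr
  }
  if (is.null(seed)) run() else with_sim_seed(seed, run())
}
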