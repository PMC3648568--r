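#' Sliding-window scan for aggregation of significant features
#'
#' Tiles each chromosome with windows of `block_size_bp` advanced by
#' `step_bp` (clipped at chromosome ends rather than discarded), assigns
#' features by the midpoint rule, and tests each window's hit count with
#' a one-sided upper-tail exact binomial test against the genome-wide
#' hit fraction:
#' `p = P(X >= hits | Binomial(gene_count, genome_rate))`.
#' A window is significant when `p < alpha`.  No multiplicity adjustment
#' is applied across windows (the raw-threshold convention of the
#' original aggregation method); see [chip_polymorphic_regions()] for a
#' genome-wide-filtered composition.
#'
#' A permutation null (`method = "permutation"`: significance flags
#' shuffled over feature positions) is available as a sensitivity check
#' on the binomial default.
#'
#' @param catalog A [gene_catalog] of features (genes or probes).
#' @param significant Logical vector along `catalog` rows: which
#'   features are hits (e.g. DEG or SFP calls); or a DiffCall table
#'   whose `feature_id`/`significant` columns are matched to the catalog.
#' @param block_size_bp,step_bp Window geometry (defaults 1000 kb /
#'   500 kb).  `step_bp` must not exceed `block_size_bp`.
#' @param alpha Per-window significance threshold (default 0.01).
#' @param chrom_lengths Named vector of chromosome lengths; defaults to
#'   the maximum feature end per chromosome.
#' @param method `"binomial"` (exact test, default) or `"permutation"`.
#' @param n_perm Permutation count for `method = "permutation"`.
#' @return A `data.frame` of GenomeWindows: `chrom`, `start`, `end`,
#'   `gene_count`, `hit_count`, `p_value`, `significant`.
#' @export
window_scan <- function(catalog, significant,
                        block_size_bp = 1e6, step_bp = 5e5,
                        alpha = 0.01, chrom_lengths = NULL,
                        method = c("binomial", "permutation"),
                        n_perm = 1000L) {
  method <- match.arg(method)
  if (step_bp > block_size_bp) {
    stop("step_bp must not exceed block_size_bp")
  }
  if (is.data.frame(significant)) {
    idx <- match(catalog$gene_id, significant$feature_id)
    significant <- significant$significant[idx]
    significant[is.na(significant)] <- FALSE
  }
  stopifnot(length(significant) == nrow(catalog))
  if (nrow(catalog) == 0L) {
    return(empty_windows())
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(catalog$end, catalog$chrom, max)
  }
  chroms <- names(chrom_lengths)
  mid <- gene_midpoint(catalog)
  n_per_step <- as.integer(ceiling(block_size_bp / step_bp))

  win_list <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + block_size_bp, len),
               stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, win_list)
  offsets <- c(0L, cumsum(vapply(win_list, nrow, 0L)))
  names(offsets) <- c(chroms, "..end")

  n_win <- nrow(windows)
  gene_count <- integer(n_win)
  hit_count <- integer(n_win)
  # each feature falls in up to ceiling(block/step) consecutive windows
  assign_rows <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    gsel <- which(catalog$chrom == ch)
    if (!length(gsel)) next
    nw_ch <- nrow(win_list[[ci]])
    base <- floor(mid[gsel] / step_bp)
    rows_g <- integer(0); rows_w <- integer(0)
    for (k in seq_len(n_per_step) - 1L) {
      wi <- base - k
      ok <- wi >= 0 & wi < nw_ch & mid[gsel] < (wi * step_bp + block_size_bp)
      rows_g <- c(rows_g, gsel[ok])
      rows_w <- c(rows_w, offsets[[ch]] + wi[ok] + 1L)
    }
    assign_rows[[ci]] <- cbind(gene = rows_g, window = rows_w)
    gene_count <- gene_count +
      tabulate(rows_w, nbins = n_win)
    hit_count <- hit_count +
      tabulate(rows_w[significant[rows_g]], nbins = n_win)
  }
  windows$gene_count <- gene_count
  windows$hit_count <- hit_count

  rate <- sum(significant) / nrow(catalog)
  if (method == "binomial") {
    p <- binom_upper_tail(windows$hit_count, windows$gene_count, rate)
  } else {
    assign_all <- do.call(rbind, assign_rows)
    counts <- matrix(0L, nrow = n_win, ncol = n_perm)
    n_hits <- sum(significant)
    for (b in seq_len(n_perm)) {
      perm <- logical(nrow(catalog))
      perm[sample.int(nrow(catalog), n_hits)] <- TRUE
      counts[, b] <- tabulate(assign_all[perm[assign_all[, "gene"]],
                                         "window"], nbins = n_win)
    }
    exceed <- rowSums(counts >= windows$hit_count)
    p <- (exceed + 1) / (n_perm + 1)
    p[windows$hit_count == 0L] <- 1
  }
  windows$p_value <- p
  windows$significant <- windows$p_value < alpha
  windows
}

binom_upper_tail <- function(hits, n, rate) {
  p <- rep(1, length(hits))
  ok <- hits > 0 & n > 0 & rate > 0
  p[ok] <- stats::pbinom(hits[ok] - 1, n[ok], rate, lower.tail = FALSE)
  pmin(p, 1)
}

empty_windows <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             gene_count = integer(0), hit_count = integer(0),
             p_value = numeric(0), significant = logical(0))
}

#' Merge significant windows into aggregation regions
#'
#' Takes the window table of one [window_scan()] and returns the maximal
#' unions of significant windows that overlap or abut.  Non-significant
#' windows are never included; regions on one chromosome are pairwise
#' disjoint by construction.
#'
#' @param windows A window `data.frame` from [window_scan()].
#' @return A `data.frame` of AggregationRegions: `chrom`, `start`,
#'   `end`, `n_windows`, `min_p`.
#' @export
merge_regions <- function(windows) {
  sig <- windows[windows$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      min_p = numeric(0)))
  }
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  # single sweep: a window joins the open region iff it overlaps or abuts
  # (start <= running end) on the same chromosome
  region_id <- integer(nrow(sig))
  rid <- 1L
  region_id[1L] <- rid
  run_end <- sig$end[1L]
  for (i in seq_len(nrow(sig))[-1L]) {
    if (sig$chrom[i] != sig$chrom[i - 1L] || sig$start[i] > run_end) {
      rid <- rid + 1L
      run_end <- sig$end[i]
    } else {
      run_end <- max(run_end, sig$end[i])
    }
    region_id[i] <- rid
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(sig)), region_id),
    function(i) {
      data.frame(chrom = sig$chrom[i[1L]],
                 start = min(sig$start[i]),
                 end = max(sig$end[i]),
                 n_windows = length(i),
                 min_p = min(sig$p_value[i]),
                 stringsAsFactors = FALSE)
    }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chip-defined polymorphic regions from hybridization calls
#'
#' Two-stage composition of [window_scan()] and [merge_regions()] on
#' probe-level differential-hybridization calls, mirroring the
#' candidate-then-selected structure of chip-based QTL-region
#' definition: candidate regions are merged runs of windows significant
#' at the per-window `alpha`; a candidate is *selected* when its best
#' window survives a genome-wide Bonferroni filter
#' (`min_p < region_alpha / n_windows`), which separates planted
#' polymorphic blocks (whose windows carry overwhelming hit excess) from
#' the handful of raw-threshold false positives expected across ~10^3
#' windows.
#'
#' @param calls DiffCall table from
#'   [call_hybridization_polymorphisms()].
#' @param probes Probe [gene_catalog] aligned with `calls`.
#' @param block_size_bp,step_bp,alpha,chrom_lengths As in
#'   [window_scan()].
#' @param region_alpha Genome-wide significance level of the selection
#'   filter (default 0.01).
#' @return A region `data.frame` as from [merge_regions()], with the
#'   unfiltered candidates in `attr(, "candidates")`.
#' @export
chip_polymorphic_regions <- function(calls, probes,
                                     block_size_bp = 1e6, step_bp = 5e5,
                                     alpha = 0.01, region_alpha = 0.01,
                                     chrom_lengths = NULL) {
  if (nrow(probes) == 0L) {
    out <- merge_regions(empty_windows())
    attr(out, "candidates") <- out
    return(out)
  }
  windows <- window_scan(probes, calls, block_size_bp = block_size_bp,
                         step_bp = step_bp, alpha = alpha,
                         chrom_lengths = chrom_lengths)
  candidates <- merge_regions(windows)
  selected <- candidates[candidates$min_p <
                           region_alpha / nrow(windows), , drop = FALSE]
  rownames(selected) <- NULL
  attr(selected, "candidates") <- candidates
  selected
}

#' Count distinct aggregation regions across tissues
#'
#' Regions computed per tissue are unioned (overlapping or abutting
#' regions merged across lists) to give the "distinct regions" count
#' reported for a BIL pair.
#'
#' @param region_list List of region `data.frame`s (one per tissue).
#' @return A merged region `data.frame`.
#' @export
union_regions <- function(region_list) {
  all_regions <- do.call(rbind, region_list)
  if (is.null(all_regions) || nrow(all_regions) == 0L) {
    return(merge_regions(empty_windows()))
  }
  pseudo <- data.frame(chrom = all_regions$chrom,
                       start = all_regions$start, end = all_regions$end,
                       gene_count = NA_integer_, hit_count = NA_integer_,
                       p_value = all_regions$min_p, significant = TRUE,
                       stringsAsFactors = FALSE)
  out <- merge_regions(pseudo)
  names(out)[names(out) == "n_windows"] <- "n_members"
  out
}

#' Export regions as BED
#'
#' Writes aggregation regions as a 0-based half-open BED track via
#' `rtracklayer::export`.
#'
#' @param regions Region `data.frame` (`chrom`, `start`, `end`).
#' @param path Output path ending in `.bed`.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1,
                              end = regions$end),
    name = sprintf("region_%d", seq_len(nrow(regions)))
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
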