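#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test of the table
#' \preformatted{ [[a, b], [c, d]] }
#' with fixed margins, as used throughout the enrichment analyses
#' (rows: in set / not in set; columns: in region-or-category / not).
#' `"greater"` (the enrichment question, default) sums the upper tail
#' `P(X >= a)`; `"two_sided"` sums the probabilities of all margin-fixed
#' tables no more likely than the observed one.  A zero margin makes the
#' table degenerate: `p = 1` and the odds ratio is `NaN`.  The odds
#' ratio is the sample estimate `a*d / (b*c)` (`Inf` when only `b*c` is
#' zero).
#'
#' @param a,b,c,d Non-negative integer cell counts, `a+b+c+d > 0`.
#' @param sided `"greater"` or `"two_sided"`.
#' @return A list with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_2x2(9, 1, 1, 9)
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             sided = c("greater", "two_sided")) {
  sided <- match.arg(sided)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("empty table: a+b+c+d must be positive")
  m <- a + b          # set size
  n <- c + d          # complement size
  k <- a + c          # region/category size
  odds_ratio <- if ((a * d) == 0 && (b * c) == 0) {
    NaN
  } else if ((b * c) == 0) {
    Inf
  } else {
    (a * d) / (b * c)
  }
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(list(odds_ratio = NaN, p_value = 1))
  }
  if (sided == "greater") {
    p <- stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
  } else {
    support <- max(0, k - n):min(k, m)
    dens <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  }
  list(odds_ratio = odds_ratio, p_value = min(p, 1))
}

enrichment_row <- function(set_name, universe_size, set_size,
                           region_size, overlap, sided, genes = NULL) {
  ft <- fisher_exact_2x2(
    overlap, set_size - overlap,
    region_size - overlap,
    universe_size - set_size - region_size + overlap,
    sided = sided
  )
  row <- data.frame(
    set_name = set_name,
    universe_size = universe_size,
    set_size = set_size,
    region_or_category_size = region_size,
    overlap = overlap,
    odds_ratio = ft$odds_ratio,
    p_value = ft$p_value,
    stringsAsFactors = FALSE
  )
  row$genes <- list(if (is.null(genes)) character(0) else genes)
  row
}

#' Enrichment of DEGs within QTL intervals
#'
#' For each interval, tests the 2x2 overlap of \{in interval vs out\} x
#' \{DEG vs non-DEG\} over the chosen gene universe with
#' [fisher_exact_2x2()].  The per-interval DEG gene lists are carried in
#' the `genes` list column for downstream candidate nomination.  A
#' Benjamini-Hochberg column (`p_adj_BH`) is emitted alongside the raw
#' p-values for reference; the raw `p < 0.05` convention is what the
#' reported significance follows.
#'
#' @param calls DiffCall table (from [call_degs()]); features matched to
#'   catalog gene ids.
#' @param catalog A [gene_catalog].
#' @param intervals A [qtl_intervals()] table.
#' @param universe `"all_genes"` (whole catalog, default) or
#'   `"tested_genes"` (catalog genes present in `calls`).
#' @param assignment Gene-to-interval assignment rule; see
#'   [genes_in_interval()].
#' @param sided Sidedness of the Fisher test (default `"greater"`).
#' @return A `data.frame` of EnrichmentResults, one row per interval.
#' @export
qtl_region_enrichment <- function(calls, catalog, intervals,
                                  universe = c("all_genes",
                                               "tested_genes"),
                                  assignment = "midpoint",
                                  sided = "greater") {
  universe <- match.arg(universe)
  uni <- if (universe == "tested_genes") {
    catalog[catalog$gene_id %in% calls$feature_id, , drop = FALSE]
  } else {
    catalog
  }
  if (nrow(uni) == 0L) stop("empty gene universe")
  deg_ids <- calls$feature_id[calls$significant]
  is_deg <- uni$gene_id %in% deg_ids
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    in_iv <- uni$gene_id %in%
      genes_in_interval(uni, intervals[i, , drop = FALSE],
                        assignment = assignment)$gene_id
    enrichment_row(
      set_name = intervals$name[i],
      universe_size = nrow(uni),
      set_size = sum(is_deg),
      region_size = sum(in_iv),
      overlap = sum(is_deg & in_iv),
      sided = sided,
      genes = uni$gene_id[is_deg & in_iv]
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj_BH <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Enrichment of a gene set against annotation categories
#'
#' Tests a gene subset against every annotation category it overlaps
#' (many-to-many annotation), with the same Fisher machinery and
#' universe semantics as [qtl_region_enrichment()].  Subset genes absent
#' from the universe are dropped with a warning.
#'
#' @param genes Character vector of gene ids (the subset of interest,
#'   e.g. the DEGs within QTL regions).
#' @param annotation `data.frame` with columns `gene_id`, `namespace`,
#'   `category_id` and optionally `category_label`.
#' @param universe Character vector of gene ids forming the universe.
#' @param sided Sidedness of the Fisher test.
#' @return A `data.frame` of EnrichmentResults, one row per category
#'   with `overlap >= 1`, plus `namespace` and `p_adj_BH` columns,
#'   ordered by p-value.
#' @export
category_enrichment <- function(genes, annotation, universe,
                                sided = "greater") {
  genes <- unique(genes)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  missing <- setdiff(genes, universe)
  if (length(missing)) {
    warning(length(missing), " subset gene(s) absent from universe; ",
            "excluded")
    genes <- intersect(genes, universe)
  }
  annotation <- annotation[annotation$gene_id %in% universe, ,
                           drop = FALSE]
  if (is.null(annotation$category_label)) {
    annotation$category_label <- annotation$category_id
  }
  key <- paste(annotation$namespace, annotation$category_id, sep = "\r")
  cats <- split(annotation, key)
  rows <- lapply(cats, function(an) {
    members <- unique(an$gene_id)
    ov <- intersect(genes, members)
    if (length(ov) == 0L) return(NULL)
    row <- enrichment_row(
      set_name = paste0(an$namespace[1L], "|", an$category_label[1L]),
      universe_size = length(universe),
      set_size = length(genes),
      region_size = length(members),
      overlap = length(ov),
      sided = sided,
      genes = ov
    )
    row$namespace <- an$namespace[1L]
    row
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- enrichment_row("none", length(universe), length(genes), 0, 0,
                          sided)[0, ]
    out$namespace <- character(0)
    out$p_adj_BH <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj_BH <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an annotation table
#'
#' TSV with header columns `gene_id`, `namespace`, `category_id` and
#' optionally `category_label`.
#'
#' @param path File path.
#' @return The annotation `data.frame`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "namespace", "category_id")
  if (!all(need %in% names(df))) {
    stop("annotation table must have columns ",
         paste(need, collapse = ", "))
  }
  df
}

#' Write an enrichment table
#'
#' Serialises EnrichmentResults to TSV (the `genes` list column is
#' flattened to `";"`-separated ids), with deterministic column order.
#'
#' @param results Enrichment `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  out <- results
  out$genes <- vapply(results$genes, paste, "", collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
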