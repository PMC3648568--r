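#' Nominate candidate genes at the convergence of DEGs, aggregation
#' regions and QTL intervals
#'
#' A candidate is a gene called differentially expressed in any tissue
#' whose position (assignment rule as elsewhere) falls inside a named
#' QTL interval.  Each candidate is flagged for overlap with the DEG
#' aggregation regions, retains the set of supporting tissues and the
#' direction of the expression effect, and carries its annotation
#' categories.  The summary counts report the total DEGs-in-QTL and the
#' subset also inside aggregation regions.
#'
#' @param deg_calls Named list of DiffCall tables, one per tissue (names
#'   are the tissue labels), all on the same catalog.
#' @param regions Named list of aggregation-region tables per tissue
#'   (from [merge_regions()]), or a single region table.
#' @param intervals A [qtl_intervals()] table.
#' @param catalog The shared [gene_catalog].
#' @param assignment Gene-to-interval assignment rule.
#' @return A list with `candidates` (one row per candidate gene:
#'   `gene_id`, `chrom`, `position_bp`, `qtl_name`,
#'   `in_aggregation_region`, `tissues_supporting`, `effect_direction`,
#'   `categories`) and `counts` (named vector `in_qtl`,
#'   `in_qtl_and_region`).
#' @export
nominate_candidates <- function(deg_calls, regions, intervals, catalog,
                                assignment = "midpoint") {
  if (is.data.frame(deg_calls)) deg_calls <- list(pooled = deg_calls)
  if (is.data.frame(regions)) regions <- list(pooled = regions)
  for (tissue in names(deg_calls)) {
    unknown <- setdiff(deg_calls[[tissue]]$feature_id, catalog$gene_id)
    if (length(unknown)) {
      stop("DEG calls for ", tissue, " contain ", length(unknown),
           " feature(s) absent from the catalog (mismatched catalogs?)")
    }
  }
  region_union <- union_regions(unname(regions))
  mid <- gene_midpoint(catalog)

  sig_by_tissue <- lapply(deg_calls, function(calls) {
    calls[calls$significant, c("feature_id", "effect"), drop = FALSE]
  })
  deg_ids <- unique(unlist(lapply(sig_by_tissue, `[[`, "feature_id")))
  if (!length(deg_ids)) {
    empty <- data.frame(
      gene_id = character(0), chrom = character(0),
      position_bp = numeric(0), qtl_name = character(0),
      in_aggregation_region = logical(0)
    )
    empty$tissues_supporting <- list()
    empty$effect_direction <- numeric(0)
    empty$categories <- list()
    return(list(candidates = empty,
                counts = c(in_qtl = 0L, in_qtl_and_region = 0L)))
  }

  # assign each DEG to its QTL interval (first match; intervals are
  # disjoint in practice)
  ci <- match(deg_ids, catalog$gene_id)
  qtl_name <- rep(NA_character_, length(deg_ids))
  for (i in seq_len(nrow(intervals))) {
    inside <- catalog$chrom[ci] == intervals$chrom[i] &
      mid[ci] >= intervals$start[i] & mid[ci] < intervals$end[i]
    qtl_name[inside & is.na(qtl_name)] <- intervals$name[i]
  }
  keep <- !is.na(qtl_name)
  deg_ids <- deg_ids[keep]; ci <- ci[keep]; qtl_name <- qtl_name[keep]

  in_region <- vapply(seq_along(deg_ids), function(j) {
    any(region_union$chrom == catalog$chrom[ci[j]] &
          region_union$start <= mid[ci[j]] &
          region_union$end > mid[ci[j]])
  }, TRUE)
  tissues <- lapply(deg_ids, function(id) {
    names(sig_by_tissue)[vapply(sig_by_tissue, function(s) {
      id %in% s$feature_id
    }, TRUE)]
  })
  direction <- vapply(seq_along(deg_ids), function(j) {
    effs <- unlist(lapply(sig_by_tissue[tissues[[j]]], function(s) {
      s$effect[s$feature_id == deg_ids[j]]
    }))
    sign(mean(effs))
  }, 0)

  candidates <- data.frame(
    gene_id = deg_ids,
    chrom = catalog$chrom[ci],
    position_bp = mid[ci],
    qtl_name = qtl_name,
    in_aggregation_region = in_region,
    stringsAsFactors = FALSE
  )
  candidates$tissues_supporting <- tissues
  candidates$effect_direction <- direction
  candidates$categories <- catalog$categories[ci]
  candidates <- candidates[order(candidates$chrom,
                                 candidates$position_bp), , drop = FALSE]
  rownames(candidates) <- NULL
  list(candidates = candidates,
       counts = c(in_qtl = nrow(candidates),
                  in_qtl_and_region = sum(candidates$in_aggregation_region)))
}

#' Yield advantage over a check entry in a multi-environment trial
#'
#' Computes, per (entry, site, regime) cell, the exact integer
#' difference between the entry's yield and the check entry's yield in
#' the same site and regime, then the min and max over the requested
#' scope.  Cells whose check value is missing are excluded with a
#' warning.  With `significant_only = TRUE`, only advantages exceeding
#' the site's least significant difference (`lsd_kg_ha` column) are
#' retained for the range — the convention under which a line is said
#' to "show" a yield advantage in trial reports (cells without an LSD
#' are then dropped, with a warning).
#'
#' @param trial A trial table ([make_trial_table()] schema).
#' @param check_entry Check variety (default `"IR64"`).
#' @param regime Optional regime filter (e.g. `"stress"`).
#' @param sites Optional site/season filter.
#' @param entries Entries in scope; default all non-check entries.
#' @param significant_only Restrict to advantages exceeding the LSD.
#' @return A list of class `advantage_summary` with `advantages` (one
#'   row per cell: `entry`, `site`, `regime`, `advantage_kg_ha`,
#'   `lsd_kg_ha`, `significant`), `min_advantage` and `max_advantage`
#'   (over the retained rows).
#' @export
yield_advantage <- function(trial, check_entry = "IR64", regime = NULL,
                            sites = NULL, entries = NULL,
                            significant_only = FALSE) {
  tbl <- trial
  if (!is.null(regime)) tbl <- tbl[tbl$regime %in% regime, , drop = FALSE]
  if (!is.null(sites)) tbl <- tbl[tbl$site %in% sites, , drop = FALSE]
  if (is.null(entries)) entries <- setdiff(unique(tbl$entry), check_entry)
  check <- tbl[tbl$entry == check_entry, , drop = FALSE]
  if (nrow(check) == 0L) {
    stop("check entry ", check_entry, " absent from the trial scope")
  }
  ent <- tbl[tbl$entry %in% entries, , drop = FALSE]
  key <- function(d) paste(d$site, d$regime, sep = "\r")
  idx <- match(key(ent), key(check))
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " cell(s) without a matching check value; ",
            "excluded")
    ent <- ent[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  adv <- data.frame(
    entry = ent$entry, site = ent$site, regime = ent$regime,
    advantage_kg_ha = ent$yield_kg_ha - check$yield_kg_ha[idx],
    lsd_kg_ha = if ("lsd_kg_ha" %in% names(ent)) ent$lsd_kg_ha else NA,
    stringsAsFactors = FALSE
  )
  adv$significant <- !is.na(adv$lsd_kg_ha) &
    adv$advantage_kg_ha > adv$lsd_kg_ha
  scope <- adv
  if (significant_only) {
    if (anyNA(adv$lsd_kg_ha)) {
      warning(sum(is.na(adv$lsd_kg_ha)),
              " cell(s) without an LSD; excluded from the range")
    }
    scope <- adv[adv$significant, , drop = FALSE]
  }
  out <- list(
    advantages = adv,
    min_advantage = if (nrow(scope)) min(scope$advantage_kg_ha) else NA,
    max_advantage = if (nrow(scope)) max(scope$advantage_kg_ha) else NA,
    check_entry = check_entry,
    significant_only = significant_only
  )
  class(out) <- "advantage_summary"
  out
}

#' @export
print.advantage_summary <- function(x, ...) {
  cat(sprintf(
    "Yield advantage over %s%s: %s to %s kg/ha over %d cell(s)\n",
    x$check_entry,
    if (x$significant_only) " (LSD-significant cells)" else "",
    format(x$min_advantage), format(x$max_advantage),
    nrow(x$advantages)
  ))
  invisible(x)
}

#' Write the convergence report
#'
#' Emits the machine-readable candidate table
#' (`<prefix>_candidates.tsv`; list columns flattened to `";"`-
#' separated values) and a short human-readable markdown summary
#' (`<prefix>_summary.md`) with the DEGs-in-QTL counts and per-QTL
#' breakdown.
#'
#' @param nomination Result of [nominate_candidates()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_convergence_report <- function(nomination, prefix) {
  cand <- nomination$candidates
  flat <- cand
  flat$tissues_supporting <- vapply(cand$tissues_supporting, paste, "",
                                    collapse = ";")
  flat$categories <- vapply(cand$categories, paste, "", collapse = ";")
  tsv <- paste0(prefix, "_candidates.tsv")
  utils::write.table(flat, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md <- paste0(prefix, "_summary.md")
  lines <- c(
    "# Convergence summary",
    "",
    sprintf("- DEGs inside QTL intervals: %d",
            nomination$counts[["in_qtl"]]),
    sprintf("- ... of which inside DEG aggregation regions: %d",
            nomination$counts[["in_qtl_and_region"]]),
    "",
    "| QTL | candidates | in aggregation region |",
    "|-----|-----------:|----------------------:|"
  )
  if (nrow(cand)) {
    per_qtl <- split(cand, cand$qtl_name)
    lines <- c(lines, vapply(names(per_qtl), function(q) {
      sprintf("| %s | %d | %d |", q, nrow(per_qtl[[q]]),
              sum(per_qtl[[q]]$in_aggregation_region))
    }, ""))
  }
  writeLines(lines, md)
  invisible(c(tsv, md))
}
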