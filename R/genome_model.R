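#' Positioned gene catalogs
#'
#' A gene catalog is a `data.frame` (class `gene_catalog`) with one row per
#' positioned genomic feature and columns:
#'
#' * `gene_id` — unique feature identifier (character)
#' * `chrom` — normalized chromosome name, `"chr"` + number (character)
#' * `start`, `end` — 0-based half-open coordinates (integer-valued;
#'   `end > start`)
#' * `categories` — list column of character vectors of annotation
#'   category identifiers (possibly empty)
#'
#' All internal coordinate arithmetic in the package is 0-based half-open;
#' reporting helpers convert to the 1-based megabase style used in the
#' field ("6.8–7.3 Mb").
#'
#' @param gene_id,chrom,start,end,categories Column vectors as described
#'   above; `categories` may be `NULL` (all empty), a character vector of
#'   `";"`-separated identifiers, or a list of character vectors.
#' @return A `gene_catalog`, sorted by `(chrom, start)`.
#' @examples
#' gene_catalog(c("g1", "g2"), "chr1", c(0, 5000), c(2000, 8000))
#' @export
gene_catalog <- function(gene_id, chrom, start, end, categories = NULL) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = normalize_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  if (is.null(categories)) {
    df$categories <- replicate(nrow(df), character(0), simplify = FALSE)
  } else if (is.character(categories)) {
    df$categories <- strsplit(ifelse(is.na(categories), "", categories), ";",
                              fixed = TRUE)
  } else {
    stopifnot(is.list(categories), length(categories) == nrow(df))
    df$categories <- lapply(categories, as.character)
  }
  validate_gene_catalog(df)
  df <- df[order(df$chrom, df$start, df$end, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_catalog", "data.frame")
  df
}

validate_gene_catalog <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    dup <- df$gene_id[duplicated(df$gene_id)][1L]
    stop("duplicate gene_id in catalog: ", dup)
  }
  if (any(df$start < 0)) stop("negative start coordinate in catalog")
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1L]
    stop("end must exceed start (0-based half-open); offending gene_id: ",
         df$gene_id[bad])
  }
  invisible(df)
}

#' Normalize chromosome names
#'
#' Maps `"1"`, `"Chr1"`, `"chr01"`, `"Chr01"` etc. to the canonical
#' `"chr1"` form. Non-numeric names are lower-cased and prefixed with
#' `"chr"` if the prefix is missing.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(x) {
  x <- tolower(as.character(x))
  x <- sub("^chr", "", x)
  num <- suppressWarnings(as.integer(x))
  ifelse(is.na(num), paste0("chr", x), paste0("chr", num))
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x[, c("gene_id", "chrom", "start", "end")]),
                    10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' QTL interval tables
#'
#' Constructs a table of named genomic intervals (a `data.frame` with
#' columns `name`, `chrom`, `start`, `end`, `source`), used both for QTL
#' regions and for planted polymorphic blocks in the simulators.
#' Coordinates are 0-based half-open.
#'
#' @param name Interval names (e.g. `"qDTY2.2"`).
#' @param chrom Chromosome names (normalized on construction).
#' @param start,end Interval bounds in bp, `start < end`.
#' @param source Either `"chip_defined"` (interval delimited by array
#'   hybridization polymorphism) or `"marker_defined"`.
#' @return A `data.frame` of intervals.
#' @export
qtl_intervals <- function(name, chrom, start, end,
                          source = c("chip_defined", "marker_defined")) {
  source <- match.arg(source)
  df <- data.frame(
    name = as.character(name),
    chrom = normalize_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    source = rep(source, length.out = length(name)),
    stringsAsFactors = FALSE
  )
  if (any(df$start >= df$end)) stop("interval start must be < end")
  df
}

#' The four rice drought-yield QTL intervals
#'
#' The chip-delimited polymorphic regions harbouring the grain-yield-
#' under-drought QTL qDTY2.2 (chr2 6.8–7.3 Mb), qDTY4.1 (chr4 6.7–7.2 Mb),
#' qDTY9.1 (chr9 14.6–16.5 Mb) and qDTY10.1 (chr10 18.6–19.3 Mb), in
#' internal 0-based bp coordinates. These are the default planted
#' intervals of the synthetic-data module.
#'
#' @return A `qtl_intervals` table with four rows.
#' @export
default_qtl_intervals <- function() {
  qtl_intervals(
    name = c("qDTY2.2", "qDTY4.1", "qDTY9.1", "qDTY10.1"),
    chrom = c("chr2", "chr4", "chr9", "chr10"),
    start = c(6.8e6, 6.7e6, 14.6e6, 18.6e6),
    end = c(7.3e6, 7.2e6, 16.5e6, 19.3e6),
    source = "chip_defined"
  )
}

#' Format an interval in display (megabase) style
#'
#' @param chrom,start,end Interval in internal 0-based bp coordinates.
#' @return Character, e.g. `"chr2:6.8-7.3 Mb"`.
#' @export
format_interval_mb <- function(chrom, start, end) {
  sprintf("%s:%.1f-%.1f Mb", chrom, start / 1e6, end / 1e6)
}

#' Read a gene catalog from disk
#'
#' Supports three on-disk dialects:
#'
#' * `"tsv"` — tab-separated with header columns `gene_id`, `chrom`,
#'   `start`, `end` and optionally `categories` (`";"`-separated);
#'   coordinates 0-based half-open (the package's native dump format).
#' * `"bed"` — standard BED, 0-based half-open, name column as `gene_id`.
#' * `"gff3"` — standard GFF3, 1-based inclusive (converted on read);
#'   only `gene`-type features are kept when a `type` column is present,
#'   and the `ID` (falling back to `Name`) attribute supplies `gene_id`.
#'
#' BED and GFF3 are parsed with `rtracklayer::import`. Chromosome names
#' are normalized. Records are returned sorted by `(chrom, start)`.
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"bed"`, `"gff3"`. Defaults to a guess
#'   from the file extension.
#' @return A [gene_catalog].
#' @export
read_gene_catalog <- function(path, format = c("tsv", "bed", "gff3")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(format) > 1L) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bed", "gff3", "gff")) {
      if (ext == "bed") "bed" else "gff3"
    } else "tsv"
  }
  format <- match.arg(format, c("tsv", "bed", "gff3"))
  switch(format,
    tsv = read_catalog_tsv(path),
    bed = read_catalog_track(path, "BED"),
    gff3 = read_catalog_track(path, "GFF3")
  )
}

read_catalog_tsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(is.na(suppressWarnings(as.numeric(df$start))) |
                 is.na(suppressWarnings(as.numeric(df$end))))
  if (length(bad)) {
    stop("parse error in ", path, " at line ", bad[1L] + 1L,
         ": non-numeric coordinate")
  }
  cats <- if ("categories" %in% names(df)) as.character(df$categories) else NULL
  gene_catalog(df$gene_id, df$chrom, df$start, df$end, cats)
}

read_catalog_track <- function(path, fmt) {
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0L) {
    return(gene_catalog(character(0), character(0), numeric(0), numeric(0)))
  }
  md <- S4Vectors::mcols(gr)
  if (fmt == "GFF3" && "type" %in% names(md)) {
    keep <- as.character(md$type) == "gene"
    if (any(keep)) {
      gr <- gr[keep]
      md <- S4Vectors::mcols(gr)
    }
  }
  ids <- NULL
  for (field in c("ID", "Name", "name")) {
    if (field %in% names(md) && !all(is.na(md[[field]]))) {
      ids <- as.character(md[[field]])
      break
    }
  }
  if (is.null(ids)) ids <- paste0("feature_", seq_along(gr))
  # GRanges is 1-based inclusive regardless of source dialect; convert to
  # the internal 0-based half-open convention.
  gene_catalog(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}

#' Write a gene catalog to disk
#'
#' `"tsv"` writes the native dump (deterministic column order
#' `gene_id, chrom, start, end, categories`; 0-based half-open).
#' `"bed"` writes standard BED via `rtracklayer::export`.
#'
#' @param catalog A [gene_catalog].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_gene_catalog <- function(catalog, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(
      gene_id = catalog$gene_id,
      chrom = catalog$chrom,
      start = catalog$start,
      end = catalog$end,
      categories = vapply(catalog$categories, paste, "", collapse = ";"),
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = catalog$chrom,
      ranges = IRanges::IRanges(start = catalog$start + 1, end = catalog$end),
      name = catalog$gene_id
    )
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}

gene_midpoint <- function(catalog) {
  floor((catalog$start + catalog$end) / 2)
}

#' Select catalog genes falling in an interval
#'
#' Membership is decided by the configured assignment rule: `"midpoint"`
#' (default; the gene's midpoint `floor((start+end)/2)` must lie in the
#' half-open interval, so each gene belongs to at most one interval of a
#' non-overlapping set), `"start"` (gene start in interval), or
#' `"any_overlap"` (non-empty intersection).
#'
#' @param catalog A [gene_catalog].
#' @param interval A single-row interval (`chrom`, `start`, `end`), e.g.
#'   one row of [qtl_intervals()].
#' @param assignment Assignment rule; see above.
#' @return The subset of `catalog` rows in the interval, order preserved.
#'   An interval on a chromosome absent from the catalog yields an empty
#'   subset with a warning.
#' @export
genes_in_interval <- function(catalog, interval,
                              assignment = c("midpoint", "start",
                                             "any_overlap")) {
  assignment <- match.arg(assignment)
  stopifnot(nrow(interval) == 1L)
  chrom <- normalize_chrom(interval$chrom)
  if (!chrom %in% catalog$chrom) {
    warning("chromosome ", chrom, " not present in catalog")
    return(catalog[integer(0), , drop = FALSE])
  }
  on_chrom <- catalog$chrom == chrom
  keep <- switch(assignment,
    midpoint = {
      mid <- gene_midpoint(catalog)
      on_chrom & mid >= interval$start & mid < interval$end
    },
    start = on_chrom & catalog$start >= interval$start &
      catalog$start < interval$end,
    any_overlap = on_chrom & catalog$start < interval$end &
      catalog$end > interval$start
  )
  catalog[keep, , drop = FALSE]
}
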