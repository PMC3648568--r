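#' Row-wise Welch two-sample t-tests
#'
#' Vectorised Welch (unequal-variance) t-tests of each matrix row between
#' two column groups, as used for per-gene differential expression and
#' per-probe differential hybridization.  Effect is `mean(x1) - mean(x2)`
#' per row.  Rows where both groups have zero variance get `p = 1` when
#' the means are equal; when the means differ in that degenerate case the
#' p-value is the smallest representable positive double (the p -> 0
#' limit), keeping p in (0, 1].
#'
#' @param x1,x2 Numeric matrices with equal row counts (rows = features,
#'   columns = replicates of each group); each must have >= 2 columns.
#' @return A `data.frame` with `effect`, `t`, `df`, `p_value` per row.
#' @export
welch_t_rows <- function(x1, x2) {
  stopifnot(is.matrix(x1), is.matrix(x2), nrow(x1) == nrow(x2))
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 replicates")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    equal <- degenerate & (m1 == m2)
    p[equal] <- 1
    p[degenerate & !equal] <- .Machine$double.xmin
    tt[equal] <- 0
    df[degenerate] <- NA_real_
  }
  data.frame(effect = m1 - m2, t = tt, df = df, p_value = p,
             row.names = NULL)
}

diff_calls <- function(ids, effect, p_value, alpha, contrast) {
  data.frame(
    feature_id = ids,
    effect = effect,
    p_value = p_value,
    significant = p_value < alpha,
    contrast = contrast,
    stringsAsFactors = FALSE
  )
}

#' Call differentially expressed genes between a +QTL/−QTL line pair
#'
#' Per-gene Welch t-test of log2 expression between the +QTL and −QTL
#' line of one BIL pair within a tissue.  Following the line-contrast
#' design (lines are compared rather than drought treatments), the two
#' water-stress levels are pooled as replicates of the line by default;
#' restrict `stress` for a per-stress contrast.  The effect sign is
#' +QTL minus −QTL.  Significance is the raw `p < alpha` rule with no
#' multiplicity adjustment.
#'
#' @param expression Genes x samples log2 matrix (such as
#'   `simulate_expression()$expression`).
#' @param samples Sample sheet with `sample_id`, `line_id`, `tissue`,
#'   `stress` columns matching the matrix columns.
#' @param pair Character vector `c(plus_line, minus_line)` of line ids.
#' @param tissue Tissue to test (`"root"`, `"leaf"` or `"panicle"`).
#' @param stress Stress levels pooled as replicates; default both FTSW
#'   levels.
#' @param alpha Significance threshold on the raw p-value (default
#'   0.001, the expression-contrast convention).
#' @return A `data.frame` of DiffCalls: `feature_id`, `effect`,
#'   `p_value`, `significant`, `contrast`.
#' @export
call_degs <- function(expression, samples, pair, tissue,
                      stress = c("FTSW_0.5", "FTSW_0.2"),
                      alpha = 0.001) {
  stopifnot(length(pair) == 2L)
  sel <- samples[samples$tissue == tissue & samples$stress %in% stress, ,
                 drop = FALSE]
  plus_ids <- sel$sample_id[sel$line_id == pair[1L]]
  minus_ids <- sel$sample_id[sel$line_id == pair[2L]]
  for (grp in list(c(pair[1L], length(plus_ids)),
                   c(pair[2L], length(minus_ids)))) {
    if (as.integer(grp[2L]) < 2L) {
      stop("fewer than 2 replicates for group ", grp[1L],
           " (tissue ", tissue, ")")
    }
  }
  res <- welch_t_rows(expression[, plus_ids, drop = FALSE],
                      expression[, minus_ids, drop = FALSE])
  diff_calls(rownames(expression), res$effect, res$p_value, alpha,
             "expression_p001")
}

#' Call differentially hybridized probes between two lines
#'
#' Per-probe Welch t-test of genomic-DNA hybridization intensity between
#' the two lines of a BIL pair; a significant probe is a single-feature
#' polymorphism (SFP) candidate indicating sequence divergence.  Raw
#' `p < alpha` (default 0.05), no multiplicity adjustment.
#'
#' @param intensity Probes x samples log2 intensity matrix.
#' @param samples Sample sheet with `sample_id` and `line_id`.
#' @param pair Character vector `c(plus_line, minus_line)`.
#' @param alpha Significance threshold (default 0.05).
#' @return A `data.frame` of DiffCalls with contrast
#'   `"hybridization_p005"`.
#' @export
call_hybridization_polymorphisms <- function(intensity, samples, pair,
                                             alpha = 0.05) {
  stopifnot(length(pair) == 2L)
  if (nrow(intensity) == 0L) {
    return(diff_calls(character(0), numeric(0), numeric(0), alpha,
                      character(0)))
  }
  plus_ids <- samples$sample_id[samples$line_id == pair[1L]]
  minus_ids <- samples$sample_id[samples$line_id == pair[2L]]
  for (grp in list(c(pair[1L], length(plus_ids)),
                   c(pair[2L], length(minus_ids)))) {
    if (as.integer(grp[2L]) < 2L) {
      stop("fewer than 2 replicates for group ", grp[1L])
    }
  }
  res <- welch_t_rows(intensity[, plus_ids, drop = FALSE],
                      intensity[, minus_ids, drop = FALSE])
  diff_calls(rownames(intensity), res$effect, res$p_value, alpha,
             "hybridization_p005")
}

#' Write / read DiffCall tables
#'
#' Deterministic-column-order TSV serialisation of DiffCall tables.
#'
#' @param calls A DiffCall `data.frame`.
#' @param path File path.
#' @return `path` (write) or the DiffCall `data.frame` (read).
#' @export
write_diff_calls <- function(calls, path) {
  utils::write.table(
    calls[, c("feature_id", "effect", "p_value", "significant",
              "contrast")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_diff_calls
#' @export
read_diff_calls <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
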