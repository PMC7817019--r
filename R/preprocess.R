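#' Cell-filtering thresholds
#'
#' Bundles the thresholds used by [filter_cells()]. Cells must express more
#' than `min_genes` genes and have a total UMI count above `min_counts`;
#' afterwards cells in the extreme tails of the total-count distribution are
#' clipped (`clip_percentile` per tail, default 0.5%).
#'
#' @param min_genes keep cells with strictly more than this many expressed
#'   (nonzero) genes.
#' @param min_counts keep cells with total count strictly above this value.
#' @param clip_percentile fraction in `[0, 0.5)` removed from each tail of
#'   the per-cell total-count distribution after thresholding.
#' @param min_cells gene-filter threshold carried along for
#'   [preprocess_counts()]: genes must be expressed in strictly more than
#'   `min_cells` cells.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(min_genes = 0, min_counts = 0,
                        clip_percentile = 0.005, min_cells = 10) {
  stopifnot(min_genes >= 0, min_counts >= 0, min_cells >= 0)
  if (clip_percentile < 0 || clip_percentile >= 0.5)
    stop("`clip_percentile` must lie in [0, 0.5)", call. = FALSE)
  structure(list(min_genes = min_genes, min_counts = min_counts,
                 clip_percentile = clip_percentile, min_cells = min_cells),
            class = "filter_spec")
}

#' Filter cells on expressed-gene and total-count thresholds
#'
#' Applies, in order: (1) keep cells with more than `spec$min_genes`
#' expressed genes and total count above `spec$min_counts`; (2) among the
#' survivors, drop cells whose total count falls below the
#' `clip_percentile` quantile or above the `1 - clip_percentile` quantile
#' of the per-cell totals. Row order of survivors is preserved.
#'
#' @param x raw count matrix, cells in rows, genes in columns (dense or
#'   sparse).
#' @param spec a [filter_spec()].
#' @return The filtered count matrix.
#' @export
filter_cells <- function(x, spec = filter_spec()) {
  x <- .as_input_matrix(x)
  .check_labels(x)
  if (nrow(x) == 0L) stop("`x` has no cells", call. = FALSE)
  if (any(x < 0)) stop("counts must be nonnegative", call. = FALSE)
  totals <- .cell_totals(x)
  n_genes <- as.numeric(if (.is_sparse(x)) Matrix::rowSums(x > 0) else rowSums(x > 0))

  keep <- n_genes > spec$min_genes
  if (!any(keep))
    stop(sprintf("all cells removed by min_genes = %g", spec$min_genes),
         call. = FALSE)
  keep2 <- keep & totals > spec$min_counts
  if (!any(keep2))
    stop(sprintf("all cells removed by min_counts = %g", spec$min_counts),
         call. = FALSE)

  idx <- which(keep2)
  if (spec$clip_percentile > 0) {
    tt <- totals[idx]
    lo <- quantile(tt, spec$clip_percentile, names = FALSE, type = 7)
    hi <- quantile(tt, 1 - spec$clip_percentile, names = FALSE, type = 7)
    idx <- idx[tt >= lo & tt <= hi]
    if (length(idx) == 0L)
      stop(sprintf("all cells removed by clip_percentile = %g",
                   spec$clip_percentile), call. = FALSE)
  }
  x[idx, , drop = FALSE]
}

#' Filter genes on the number of expressing cells
#'
#' Keeps genes with nonzero counts in strictly more than `min_cells` cells.
#' Column order of survivors is preserved. Note the strict inequality: with
#' `min_cells = 0` a gene must be expressed in at least one cell to survive.
#'
#' @param x raw count matrix, cells in rows, genes in columns.
#' @param min_cells nonnegative support threshold.
#' @return The filtered count matrix.
#' @export
filter_genes <- function(x, min_cells = 10) {
  x <- .as_input_matrix(x)
  .check_labels(x)
  stopifnot(min_cells >= 0)
  support <- as.numeric(if (.is_sparse(x)) Matrix::colSums(x > 0) else colSums(x > 0))
  keep <- support > min_cells
  if (!any(keep))
    stop(sprintf("all genes removed by min_cells = %g", min_cells),
         call. = FALSE)
  x[, keep, drop = FALSE]
}

#' Median depth normalization
#'
#' Rescales each cell so that its total count equals the median of the
#' per-cell totals, removing depth differences while keeping the count
#' scale of a typical cell.
#'
#' @param x count (or nonnegative expression) matrix, cells in rows.
#' @return The depth-normalized matrix (same storage class).
#' @export
median_normalize <- function(x) {
  x <- .as_input_matrix(x)
  totals <- .cell_totals(x)
  if (any(totals <= 0))
    stop("cells with zero total count present; run filter_cells() first",
         call. = FALSE)
  target <- median(totals)
  .scale_rows(x, target / totals)
}

#' Freeman-Tukey variance-stabilizing transform
#'
#' Maps each entry `x` to `sqrt(x) + sqrt(x + 1) - 1`. The `-1` shift makes
#' the transform fix zero, so the sparsity pattern is preserved exactly.
#' For Poisson-distributed counts the transformed values have approximately
#' constant variance (close to 1) across the whole intensity range, which
#' keeps highly and lowly expressed genes on comparable footing when
#' building a neighbor graph.
#'
#' @param x nonnegative matrix (dense or sparse).
#' @return The transformed matrix with identical sparsity pattern.
#' @export
freeman_tukey <- function(x) {
  x <- .as_input_matrix(x)
  if (any(x < 0)) stop("freeman_tukey() requires nonnegative entries",
                       call. = FALSE)
  .map_nonzeros(x, function(v) sqrt(v) + sqrt(v + 1) - 1)
}

#' Standard count preprocessing pipeline
#'
#' Convenience wrapper chaining [filter_cells()], [filter_genes()],
#' [median_normalize()] and (optionally) [freeman_tukey()], in that order.
#' The gene filter runs after the cell filter so gene support counts refer
#' to retained cells.
#'
#' @param x raw count matrix, cells in rows, genes in columns.
#' @param spec a [filter_spec()].
#' @param transform `"ftt"` (default) or `"none"`.
#' @return The preprocessed expression matrix.
#' @export
preprocess_counts <- function(x, spec = filter_spec(),
                              transform = c("ftt", "none")) {
  transform <- match.arg(transform)
  x <- filter_cells(x, spec)
  x <- filter_genes(x, spec$min_cells)
  x <- median_normalize(x)
  if (transform == "ftt") x <- freeman_tukey(x)
  x
}
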