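#' Mean within-group Pearson correlation
#'
#' For every pair of cells known to belong to the same group, computes the
#' Pearson correlation of their gene-expression vectors, and averages over
#' all such pairs pooled across groups. Higher values mean cells of the
#' same type have more similar profiles — the target of denoising on
#' mixture benchmarks where within-group differences are pure technical
#' noise. Pairs involving a zero-variance cell vector are skipped with a
#' warning; the number skipped is attached as attribute `n_skipped`.
#'
#' @param x expression matrix, cells in rows.
#' @param groups per-cell group labels (length `nrow(x)`).
#' @return Scalar in `[-1, 1]`.
#' @export
within_group_mean_correlation <- function(x, groups) {
  x <- .dense(.as_input_matrix(x, "x"))
  if (length(groups) != nrow(x))
    stop("`groups` must have one label per cell", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2))
    stop("every group needs at least 2 cells", call. = FALSE)
  total <- 0; n_pairs <- 0L; n_skipped <- 0L
  for (g in names(tab)) {
    rows <- x[groups == g, , drop = FALSE]
    sds <- apply(rows, 1L, sd)
    ok <- sds > 0
    n_cells <- nrow(rows)
    if (any(!ok)) {
      skipped_here <- sum(!ok) * (n_cells - 1L) - choose(sum(!ok), 2)
      n_skipped <- n_skipped + as.integer(skipped_here)
      rows <- rows[ok, , drop = FALSE]
    }
    if (nrow(rows) >= 2L) {
      cm <- cor(t(rows))
      total <- total + sum(cm[upper.tri(cm)])
      n_pairs <- n_pairs + choose(nrow(rows), 2)
    }
  }
  if (n_skipped > 0L)
    warning(sprintf("skipped %d pair(s) with a zero-variance cell", n_skipped),
            call. = FALSE)
  if (n_pairs == 0L) stop("no valid within-group pair", call. = FALSE)
  out <- total / n_pairs
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Mean squared error to the generating truth
#'
#' Compares an expression matrix with the ground-truth mean of each cell's
#' group, optionally after rescaling every true mean profile to a common
#' total (so depth-normalized data is compared on its own scale) and
#' applying the Freeman-Tukey transform (so FTT-space data is compared in
#' FTT space).
#'
#' @param x expression matrix, cells in rows.
#' @param truth a `ground_truth` from the synthetic generators.
#' @param target_total if non-`NULL`, rescale each group's true mean
#'   profile so it sums to this value before comparison (set it to the
#'   median per-cell total used in normalization).
#' @param transform `"none"` (default) or `"ftt"` applied to the truth
#'   means.
#' @return Nonnegative scalar.
#' @export
mse_to_truth <- function(x, truth, target_total = NULL,
                         transform = c("none", "ftt")) {
  transform <- match.arg(transform)
  x <- .dense(.as_input_matrix(x, "x"))
  stopifnot(inherits(truth, "ground_truth"))
  tm <- truth$true_means
  labels <- truth$group_labels
  if (nrow(tm) == nrow(x) && nrow(tm) > length(unique(labels))) {
    # full per-cell mean matrix (low-rank generator)
    T_full <- tm
  } else {
    if (length(labels) != nrow(x))
      stop("truth labels do not match the number of cells", call. = FALSE)
    if (!is.null(target_total))
      tm <- tm / rowSums(tm) * target_total
    T_full <- tm[labels, , drop = FALSE]
  }
  if (ncol(T_full) != ncol(x))
    stop("gene dimension mismatch between `x` and `truth`", call. = FALSE)
  if (transform == "ftt") T_full <- .dense(freeman_tukey(T_full))
  mean((x - T_full)^2)
}
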