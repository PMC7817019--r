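#' Binomial count splitting
#'
#' Splits every UMI count `c` into two independent halves, `Binomial(c, p)`
#' and the remainder. Because molecule counts are (approximately) Poisson,
#' the two halves are statistically independent given the underlying
#' expression rate, so one half can serve as a validation target for a
#' model fit on the other — molecular cross-validation.
#'
#' @param x integer count matrix, cells in rows.
#' @param p fraction of each count expected in the first half (0 < p < 1).
#' @param seed integer seed.
#' @return A `count_split`: list with integer matrices `x_j`, `x_jc`
#'   (entrywise `x_j + x_jc` equals the input), `p` and `seed`.
#' @export
binomial_split <- function(x, p = 0.5, seed = 0L) {
  x <- .as_input_matrix(x, "x")
  stopifnot(p > 0, p < 1)
  vals <- if (.is_sparse(x)) x@x else as.numeric(x)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("binomial_split() requires nonnegative integer counts", call. = FALSE)
  set.seed(as.integer(seed))
  if (.is_sparse(x)) {
    xj <- x
    xj@x <- as.numeric(rbinom(length(x@x), size = as.integer(round(x@x)),
                              prob = p))
    xj <- Matrix::drop0(xj)
    xjc <- Matrix::drop0(x - xj)
  } else {
    xj <- x
    xj[] <- rbinom(length(x), size = as.integer(round(x)), prob = p)
    xjc <- x - xj
  }
  structure(list(x_j = xj, x_jc = xjc, p = p, seed = as.integer(seed)),
            class = "count_split")
}

# Rank-r PCA reconstruction of a dense matrix (gene-centered).
.pca_reconstruct <- function(y, sv, center, r) {
  if (r == 0L) return(matrix(rep(center, each = nrow(y)), nrow(y)))
  ur <- sv$u[, seq_len(r), drop = FALSE]
  dr <- sv$d[seq_len(r)]
  vr <- sv$v[, seq_len(r), drop = FALSE]
  rec <- ur %*% (dr * t(vr))
  sweep(rec, 2L, center, "+")
}

#' Molecular cross-validation for PCA rank selection
#'
#' For each candidate rank `r`, fits PCA on one count half, reconstructs it
#' at rank `r`, and scores the reconstruction against the held-out half
#' (depth-rescaled by `p / (1 - p)` so both halves live on the same
#' expected scale). Because the held-out noise is independent, the loss
#' curve is U-shaped: too few components underfit the signal, too many fit
#' the training half's noise. With `normalize = TRUE` (default) both
#' halves are median-normalized and Freeman-Tukey transformed first —
#' matching the space the denoiser operates in — and the rank is chosen on
#' that transformed loss; the raw-count loss is reported alongside.
#'
#' @param split a `count_split` from [binomial_split()].
#' @param rank_grid integer vector of candidate ranks.
#' @param normalize compute the selection loss in normalized/transformed
#'   space (default `TRUE`).
#' @return A `mcv_result`: list with `rank` (selected), `curve` (data.frame
#'   of rank, loss and loss_raw) and `normalize`.
#' @export
mcv_rank_select <- function(split, rank_grid, normalize = TRUE) {
  stopifnot(inherits(split, "count_split"), length(rank_grid) > 0)
  rank_grid <- sort(unique(as.integer(rank_grid)))
  xj <- .dense(split$x_j)
  xjc <- .dense(split$x_jc) * (split$p / (1 - split$p))
  if (all(xj == 0) || all(split$x_jc == 0))
    stop("one half of the split is all zero; counts too shallow for MCV",
         call. = FALSE)
  if (max(rank_grid) > min(dim(xj)))
    stop("rank grid exceeds matrix dimensions", call. = FALSE)

  loss_for <- function(train, test) {
    center <- colMeans(train)
    sv <- svd(sweep(train, 2L, center, "-"))
    vapply(rank_grid, function(r)
      mean((.pca_reconstruct(train, sv, center, r) - test)^2), numeric(1))
  }

  loss_raw <- loss_for(xj, xjc)
  if (normalize) {
    tj <- .dense(freeman_tukey(median_normalize(split$x_j)))
    tjc <- .dense(freeman_tukey(median_normalize(split$x_jc)))
    loss_tr <- loss_for(tj, tjc)
  } else {
    loss_tr <- loss_raw
  }
  curve <- data.frame(rank = rank_grid, loss = loss_tr, loss_raw = loss_raw)
  structure(list(rank = rank_grid[which.min(loss_tr)], curve = curve,
                 normalize = normalize),
            class = "mcv_result")
}

#' @exportS3Method base::print
print.mcv_result <- function(x, ...) {
  cat(sprintf("MCV rank selection over {%s}: rank* = %d (%s-space loss)\n",
              paste(range(x$curve$rank), collapse = ".."), x$rank,
              if (x$normalize) "transformed" else "raw"))
  invisible(x)
}
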