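#' Column standardization
#'
#' Centers every gene column to mean zero and scales to unit standard
#' deviation (population convention, divisor `n`). Zero-variance columns
#' cannot be scaled and are dropped with a warning.
#'
#' @param x expression matrix, cells in rows.
#' @return Dense standardized matrix (possibly with fewer columns).
#' @export
standardize_columns <- function(x) {
  x <- .dense(.as_input_matrix(x, "x"))
  n <- nrow(x)
  mu <- colMeans(x)
  sig <- sqrt(colMeans(x^2) - mu^2)   # population sd
  keep <- sig > 0
  if (!any(keep))
    stop("all columns are constant; nothing to standardize", call. = FALSE)
  if (!all(keep))
    warning(sprintf("dropped %d zero-variance column(s)", sum(!keep)),
            call. = FALSE)
  sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-"),
        2L, sig[keep], "/")
}

#' Singular-value variance spectrum
#'
#' Computes the singular values of the (by default standardized) matrix,
#' discards values below the numerical-rank cutoff
#' `max(S) * max(m, n) * epsilon` (with `epsilon` the 32-bit float machine
#' epsilon, `2^-23`), and summarizes the variance structure: the relative
#' variance `eta2_i = s_i^2 / sum(s^2)` carried by each retained component,
#' its cumulative sum, and per-component condition numbers
#' `kappa_i = s_i / s_min`. A denoised matrix whose variance collapses into
#' a handful of components (small [components_for_fraction()]) has been
#' oversmoothed.
#'
#' @param x matrix to analyze, cells in rows.
#' @param standardize standardize columns first (default `TRUE`).
#' @param epsilon override the rank-cutoff machine epsilon.
#' @return A `variance_spectrum`: list with `singular_values` (retained,
#'   nonincreasing), `relative_variance`, `cumulative`, `condition_numbers`,
#'   `numerical_rank` and `rank_epsilon`.
#' @export
variance_spectrum <- function(x, standardize = TRUE, epsilon = NULL) {
  x <- .dense(.as_input_matrix(x, "x"))
  if (standardize) x <- standardize_columns(x)
  if (is.null(epsilon)) epsilon <- .EPS32
  s <- svd(x, nu = 0, nv = 0)$d
  cutoff <- max(s) * max(dim(x)) * epsilon
  s <- s[s > cutoff]
  eta2 <- s^2 / sum(s^2)
  structure(list(singular_values = s,
                 relative_variance = eta2,
                 cumulative = cumsum(eta2),
                 condition_numbers = s / s[length(s)],
                 numerical_rank = length(s),
                 rank_epsilon = epsilon),
            class = "variance_spectrum")
}

#' @exportS3Method base::print
print.variance_spectrum <- function(x, ...) {
  cat(sprintf("variance spectrum: numerical rank %d, leading eta2 = %.4f\n",
              x$numerical_rank, x$relative_variance[1]))
  invisible(x)
}

#' Components needed to explain a variance fraction
#'
#' Smallest number of leading components whose cumulative relative
#' variance reaches `fraction`.
#'
#' @param spectrum a `variance_spectrum`.
#' @param fraction target fraction in `(0, 1]`.
#' @return Integer component count.
#' @export
components_for_fraction <- function(spectrum, fraction) {
  stopifnot(inherits(spectrum, "variance_spectrum"),
            fraction > 0, fraction <= 1)
  # small slack so fraction = 1 is reached despite rounding in cumsum
  which(spectrum$cumulative >= fraction - 1e-12)[1L]
}
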