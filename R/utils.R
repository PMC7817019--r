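#' @importFrom methods as is
#' @importFrom stats median prcomp quantile rbinom rlnorm rmultinom rnbinom
#'   rnorm rpois runif sd cor
#' @importFrom Matrix Diagonal colSums rowSums t diag sparseMatrix readMM
NULL

# Coerce any accepted matrix input to a Matrix-package or base matrix,
# preserving sparsity. Accepts base matrix, dgCMatrix and friends.
.as_input_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) return(x)
  if (is(x, "sparseMatrix")) return(as(as(x, "CsparseMatrix"), "generalMatrix"))
  if (is(x, "Matrix")) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  stop(sprintf("`%s` must be a matrix, sparse Matrix or data.frame", arg),
       call. = FALSE)
}

.is_sparse <- function(x) is(x, "sparseMatrix")

# Row-scale a (possibly sparse) matrix by per-row factors.
.scale_rows <- function(x, factors) {
  stopifnot(length(factors) == nrow(x))
  if (.is_sparse(x)) {
    Diagonal(x = factors) %*% x
  } else {
    x * factors
  }
}

.dense <- function(x) {
  if (is.matrix(x)) x else as.matrix(x)
}

# Apply a scalar function elementwise while preserving the sparse support.
# `f` must map 0 to 0 for this to be exact.
.map_nonzeros <- function(x, f) {
  if (.is_sparse(x)) {
    x <- as(as(x, "CsparseMatrix"), "generalMatrix")
    x@x <- f(x@x)
    x
  } else {
    f(x)
  }
}

.check_labels <- function(x) {
  rn <- rownames(x)
  cn <- colnames(x)
  if (!is.null(rn) && anyDuplicated(rn))
    stop("duplicate cell labels", call. = FALSE)
  if (!is.null(cn) && anyDuplicated(cn))
    stop("duplicate gene labels", call. = FALSE)
  invisible(x)
}

.cell_totals <- function(x) {
  as.numeric(if (.is_sparse(x)) Matrix::rowSums(x) else rowSums(x))
}

# Machine epsilon of an IEEE 32-bit float; used for the numerical-rank cutoff.
.EPS32 <- 2^-23
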